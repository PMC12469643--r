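# Rate-table I/O (CSV and a minimal NMR-STAR loop reader) and run config.

.RATE_COLS <- c("residue", "r1", "r1_err", "noe", "noe_err",
                "eta_xy", "eta_xy_err")

#' Read a per-residue relaxation table
#'
#' Reads the standard rates schema (\code{residue, r1, r1_err, noe,
#' noe_err, eta_xy, eta_xy_err}) from CSV/TSV.  Empty cells become NA
#' (missing, never zero-filled); residue numbering is preserved as given.
#'
#' @param path file path.
#' @param format \code{"csv"} (default; delimiter sniffed between comma and
#'   tab) or \code{"nmrstar"} (see \code{\link{read_nmrstar_rates}}).
#' @return Data frame in the standard schema (columns absent from the file
#'   are filled with NA).
#' @export
read_relaxation_table <- function(path, format = c("csv", "nmrstar")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "nmrstar") return(read_nmrstar_rates(path))
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, na.strings = c("", "NA"))
  if (!"residue" %in% names(df))
    stop("malformed rates table (no 'residue' column): ", path)
  bad <- which(!is.finite(suppressWarnings(as.numeric(df$residue))))
  if (length(bad) > 0)
    stop("malformed rows (non-numeric residue) at data line(s): ",
         paste(bad, collapse = ", "))
  df$residue <- as.integer(df$residue)
  for (cl in setdiff(.RATE_COLS, names(df))) df[[cl]] <- NA_real_
  num_cols <- setdiff(.RATE_COLS, "residue")
  for (cl in num_cols) df[[cl]] <- as.numeric(df[[cl]])
  df[, union(.RATE_COLS, names(df))]
}

#' Write a per-residue relaxation table
#'
#' @param df data frame in the standard rates schema.
#' @param path output CSV path.
#' @return Invisibly, \code{path}.
#' @export
write_relaxation_table <- function(df, path) {
  stopifnot("residue" %in% names(df))
  out <- df
  for (cl in names(out)) {
    if (is.double(out[[cl]])) {
      # 17 significant digits: doubles survive the text round trip exactly
      v <- sprintf("%.17g", out[[cl]])
      v[is.na(out[[cl]])] <- ""
      out[[cl]] <- v
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Minimal NMR-STAR relaxation-loop reader
#'
#' Parses the \code{loop_}/\code{stop_} blocks of an NMR-STAR file and
#' extracts per-residue rate values from any loop whose tags include a
#' residue sequence code and a \code{Val} tag (e.g.
#' \code{_Heteronucl_T1_list} or cross-correlation loops).  Tags are mapped
#' by name, never by column position.  Values of \code{.} or \code{?}
#' become NA.
#'
#' @param path NMR-STAR file path.
#' @param value_tag regular expression selecting the value tag within a
#'   loop (default \code{"(^|\\\\.)Val$"}); the matching \code{Val_err} tag
#'   supplies errors when present.
#' @param param name the extracted rate should take in the output schema
#'   (default \code{"r1"}).
#' @return Data frame in the standard rates schema with the requested
#'   parameter (and error) filled in.
#' @examples
#' star <- system.file("extdata", "synthetic_r1_example.str",
#'                     package = "relaxsel")
#' read_nmrstar_rates(star, param = "r1")
#' @export
read_nmrstar_rates <- function(path, value_tag = "(^|\\.)Val$",
                               param = "r1") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  i <- 1; n <- length(lines)
  out <- NULL
  while (i <= n) {
    if (identical(lines[i], "loop_")) {
      j <- i + 1; tags <- character(0)
      while (j <= n && startsWith(lines[j], "_")) {
        tags <- c(tags, sub("^_", "", lines[j])); j <- j + 1
      }
      rows <- list()
      while (j <= n && !identical(lines[j], "stop_")) {
        if (!nzchar(lines[j]) || startsWith(lines[j], "#")) {
          j <- j + 1
          next
        }
        fields <- scan(text = lines[j], what = character(),
                       quiet = TRUE, strip.white = TRUE)
        if (length(fields) == length(tags))
          rows[[length(rows) + 1]] <- fields
        j <- j + 1
      }
      if (length(rows) > 0) {
        tab <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
        names(tab) <- tags
        seq_tag <- grep("(Seq_ID|Comp_index_ID)", tags, value = TRUE)
        val_tag <- grep(value_tag, tags, value = TRUE)
        err_tag <- grep("Val_err", tags, value = TRUE)
        if (length(seq_tag) >= 1 && length(val_tag) >= 1) {
          to_num <- function(x) {
            x[x %in% c(".", "?")] <- NA
            as.numeric(x)
          }
          out <- data.frame(residue = as.integer(tab[[seq_tag[1]]]),
                            val = to_num(tab[[val_tag[1]]]),
                            err = if (length(err_tag) >= 1)
                              to_num(tab[[err_tag[1]]]) else NA_real_)
        }
      }
      i <- j
    }
    i <- i + 1
  }
  if (is.null(out))
    stop("no relaxation loop with residue and value tags found in: ", path)
  df <- data.frame(residue = out$residue)
  for (cl in setdiff(.RATE_COLS, "residue")) df[[cl]] <- NA_real_
  df[[param]] <- out$val
  df[[paste0(param, "_err")]] <- out$err
  df
}

#' Load a run configuration
#'
#' Reads a YAML configuration (keys such as \code{field_mhz},
#' \code{r_nh_angstrom}, \code{delta_sigma_ppm}, \code{delta_sigma_p2_ppm},
#' \code{eta_xy_j_zero}, \code{ct_exponent_factor}, \code{rigid_ranges},
#' \code{segment_window_ns}, \code{seed}) and merges it over the defaults.
#'
#' @param path YAML file path, or NULL for pure defaults.
#' @param overrides named list applied on top of the file (e.g. from CLI
#'   flags).
#' @return Named list of resolved settings, including
#'   \code{package_version} for provenance.
#' @export
load_run_config <- function(path = NULL, overrides = list()) {
  cfg <- list(field_mhz = 600.13, r_nh_angstrom = 1.023,
              delta_sigma_ppm = -166, delta_sigma_p2_ppm = -145,
              eta_xy_j_zero = TRUE, ct_exponent_factor = 4,
              rigid_ranges = NULL, segment_window_ns = 500,
              sd_max = 0.3, jump_max = 1.0, equil_ns = 0,
              s2_min = 0.8, max_rel_err = 0.1, seed = 1L)
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    file_cfg <- yaml::read_yaml(path)
    cfg[names(file_cfg)] <- file_cfg
  }
  cfg[names(overrides)] <- overrides
  cfg$package_version <-
    as.character(utils::packageVersion("relaxsel"))
  cfg
}

# interaction_constants from a resolved config
.constants_from_config <- function(cfg) {
  interaction_constants(field_mhz = cfg$field_mhz,
                        r_nh = cfg$r_nh_angstrom,
                        delta_sigma = cfg$delta_sigma_ppm,
                        delta_sigma_p2 = cfg$delta_sigma_p2_ppm)
}
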