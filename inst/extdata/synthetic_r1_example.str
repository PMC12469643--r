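data_synthetic_r1_example
# Synthetic NMR-STAR fragment (not an archive deposit): a minimal
# heteronuclear R1 relaxation loop used to document the reader.

save_heteronucl_T1_list_1
   _Heteronucl_T1_list.Sf_category          heteronucl_T1_relaxation
   _Heteronucl_T1_list.Spectrometer_frequency_1H   600.13
   _Heteronucl_T1_list.T1_val_units         s-1

   loop_
      _T1.Comp_index_ID
      _T1.Comp_ID
      _T1.Val
      _T1.Val_err

      131 MET 0.81 0.02
      132 ALA 0.83 0.02
      133 GLY 0.80 0.03
      135 LEU 0.78 0.02
      136 SER .    .
   stop_
save_
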