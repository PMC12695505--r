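{
  "frontal":   ["Fp1", "Fp2", "F3", "F4", "F7", "F8", "Fz", "FC1", "FC2", "FC5", "FC6"],
  "central":   ["C3", "C4", "Cz"],
  "parietal":  ["P3", "P4", "P7", "P8", "Pz", "CP1", "CP2", "CP5", "CP6"],
  "temporal":  ["T7", "T8", "TP9", "TP10"],
  "occipital": ["O1", "O2", "Oz", "PO9", "PO10"]
}
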