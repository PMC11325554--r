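{
  "version": "1",
  "source": "Chu & Dalgarno (2004) / Tkatchenko & Scheffler (2009) free-atom compilation; atomic units",
  "elements": {
    "element": ["H", "He", "C", "N", "O", "Ne", "S", "Cl", "Ar", "Kr"],
    "alpha":   [4.500, 1.380, 12.00, 7.400, 5.400, 2.670, 19.60, 15.00, 11.10, 16.80],
    "c6":      [6.500, 1.460, 46.60, 24.20, 15.60, 6.380, 134.0, 94.60, 64.30, 129.6]
  }
}
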