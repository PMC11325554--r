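{
  "version": "1",
  "source": "effective electron numbers from the size-polarizability scaling inversion; dimensionless",
  "elements": {
    "element":   ["He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
                  "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar", "Kr"],
    "n_eff":     [1.74, 0.92, 1.76, 2.46, 3.20, 3.61, 4.17, 4.77, 5.47,
                  1.58, 2.69, 3.43, 4.34, 5.22, 5.89, 6.63, 7.40, 10.0],
    "n_valence": [2, 1, 2, 3, 4, 5, 6, 7, 8,
                  1, 2, 3, 4, 5, 6, 7, 8, 8]
  }
}
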