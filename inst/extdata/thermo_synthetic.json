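{
  "comment": "Synthetic thermodynamic configuration for the IDH isozymes (citrate <-> alpha-ketoglutarate, lumped with aconitase, oxidative direction). Standard Gibbs energies are illustrative synthetic values with Gaussian uncertainty; cofactor-ratio assumptions: mitochondrial NADH:NAD+ = 0.015, mitochondrial NADPH:NADP+ = 100 (CV 30%), cytosolic NADPH:NADP+ uniform on [30, 100], CO2 fixed at 1.2 mM.",
  "thermo": [
    {
      "name": "IDH1",
      "dg0_prime": -2.0,
      "dg0_sd": 1.5,
      "quotient_terms": [
        {"species": "akg_cit_ratio_cyto", "coeff": 1, "value": 2.0, "sd": 0.4},
        {"species": "CO2_M", "coeff": 1, "value": 0.0012, "dist": "fixed"},
        {"species": "NADPH_NADP_ratio_cyto", "coeff": 1, "dist": "uniform", "lo": 30, "hi": 100}
      ]
    },
    {
      "name": "IDH2",
      "dg0_prime": -2.0,
      "dg0_sd": 1.5,
      "quotient_terms": [
        {"species": "akg_cit_ratio_mito", "coeff": 1, "value": 1.2, "sd": 0.3},
        {"species": "CO2_M", "coeff": 1, "value": 0.0012, "dist": "fixed"},
        {"species": "NADPH_NADP_ratio_mito", "coeff": 1, "value": 100, "sd": 30}
      ]
    },
    {
      "name": "IDH3",
      "dg0_prime": -5.0,
      "dg0_sd": 1.5,
      "quotient_terms": [
        {"species": "akg_cit_ratio_mito", "coeff": 1, "value": 1.2, "sd": 0.3},
        {"species": "CO2_M", "coeff": 1, "value": 0.0012, "dist": "fixed"},
        {"species": "NADH_NAD_ratio_mito", "coeff": 1, "value": 0.015, "sd": 0.004}
      ]
    }
  ]
}
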