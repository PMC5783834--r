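{
  "title": "pipeline run report",
  "required": {
    "counts": [
      "n_features_kept", "n_de_pcg", "n_de_lncrna", "n_subpathways",
      "n_significant_subpathways", "n_network_pcg", "n_network_lncrna",
      "n_network_edges", "n_seeds_in_network", "n_significant_lncrna",
      "n_selected_lncrna", "n_module_pcg", "n_cerna_pairs"
    ],
    "statistics": [
      "powerlaw_slope", "powerlaw_r_squared", "score_separation_p",
      "module_avg_degree", "rest_avg_degree", "module_degree_p"
    ],
    "truth_recovery": [
      "de_pcg_recall", "de_lncrna_recall", "risk_lncrna_in_network",
      "risk_lncrna_selected", "cerna_pair_recall"
    ]
  }
}
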