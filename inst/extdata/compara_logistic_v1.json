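{
  "type": "logistic",
  "feature_names": ["ChimpDockScore", "avgD_Act", "avgD_Inact", "P_Act_dockChimp", "P_Inact"],
  "beta": 26.169,
  "alphas": {
    "ChimpDockScore": -0.0175,
    "avgD_Act": -98.582,
    "avgD_Inact": 66.953,
    "P_Act_dockChimp": 3.584,
    "P_Inact": -8.594
  },
  "ll": -407.619,
  "converged": true,
  "n_iter": null,
  "meta": {
    "version": "1",
    "model": "five-descriptor consensus logistic model for androgen-receptor binding",
    "trained_on": "CoMPARA AR training set (205 binders, 1480 non-binders)",
    "descriptors": "chimp AR docking score (kcal/mol, 0 = no pose); average Tanimoto distances to known binders and non-binders; Gaussian class-conditional densities of the docking score"
  }
}
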