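{
  "description": "Statistics of previously published five-descriptor multilinear QSAR models of logIC50 for three neurodegenerative-disease targets, as printed: dataset sizes, training/validation split sizes of the companion neural-network models, regression coefficients with standard errors and t-statistics, overall fit statistics, and the per-fold ABC-validation prediction R2 values with their printed averages. Used to recompute derived quantities (F from R2/N/k, t from B/SE, ABC averages) and check them against the printed values.",
  "targets": {
    "TrkA": {
      "dataset_size": 151,
      "ann_split": { "step": 5, "n_train": 121, "n_val": 30 },
      "mlr": {
        "N": 151, "k": 5,
        "R2": 0.866, "R2_cv": 0.855, "s2": 0.065, "F": 187.251,
        "F_prose_rounded": 187,
        "coefficients": [
          { "no": 0, "B": 31.850, "SE": 2.351, "t": 13.545, "descriptor": "Intercept" },
          { "no": 1, "B": -0.267, "SE": 0.017, "t": -15.942, "descriptor": "Highest coulombic interaction for N-H bonds" },
          { "no": 2, "B": -0.586, "SE": 0.041, "t": -14.412, "descriptor": "Number of F atoms" },
          { "no": 3, "B": 0.123, "SE": 0.010, "t": 12.637, "descriptor": "Highest e-n attraction for C-C bonds" },
          { "no": 4, "B": 0.214, "SE": 0.021, "t": 10.270, "descriptor": "Charged surface area of N atoms" },
          { "no": 5, "B": -0.066, "SE": 0.017, "t": -3.915, "descriptor": "Total point-charge component of molecular dipole" }
        ],
        "abc_pred_r2": [0.880, 0.861, 0.843],
        "abc_avg_printed": 0.861
      }
    },
    "NMDA": {
      "dataset_size": 133,
      "ann_split": { "step": 5, "n_train": 107, "n_val": 26 },
      "mlr": {
        "N": 83, "k": 5,
        "R2": 0.906, "R2_cv": 0.893, "s2": 0.123, "F": 149.268,
        "coefficients": [
          { "no": 0, "B": 52.126, "SE": 11.055, "t": 4.715, "descriptor": "Intercept" },
          { "no": 1, "B": -333.432, "SE": 34.324, "t": -9.714, "descriptor": "HACA-2/TMSA" },
          { "no": 2, "B": -0.760, "SE": 0.029, "t": -26.281, "descriptor": "Kier and Hall index (order 2)" },
          { "no": 3, "B": -10.315, "SE": 0.785, "t": -13.141, "descriptor": "Average bonding information content (order 0)" },
          { "no": 4, "B": -0.084, "SE": 0.008, "t": -10.313, "descriptor": "Lowest e-n attraction for C-N bonds" },
          { "no": 5, "B": -17.241, "SE": 3.022, "t": -5.706, "descriptor": "Average valency for C atoms" }
        ],
        "abc_pred_r2": [0.894, 0.884, 0.926],
        "abc_avg_printed": 0.901
      }
    },
    "LRRK2": {
      "dataset_size": 101,
      "ann_split": { "step": 5, "n_train": 81, "n_val": 20 },
      "mlr": {
        "N": 101, "k": 5,
        "R2": 0.721, "R2_cv": 0.683, "s2": 0.167, "F": 49.045,
        "F_prose_rounded": 49,
        "coefficients": [
          { "no": 0, "B": -11.779, "SE": 2.126, "t": -5.541, "descriptor": "Intercept" },
          { "no": 1, "B": -0.276, "SE": 0.028, "t": -9.947, "descriptor": "Highest coulombic interaction" },
          { "no": 2, "B": 8.364, "SE": 1.087, "t": 7.697, "descriptor": "Max bonding contribution of one MO" },
          { "no": 3, "B": 1.955, "SE": 0.954, "t": 2.048, "descriptor": "RNCG relative negative charge" },
          { "no": 4, "B": 2883.443, "SE": 389.061, "t": 7.411, "descriptor": "Max electrophilic reactivity index for H atoms" },
          { "no": 5, "B": -35.897, "SE": 8.661, "t": -4.145, "descriptor": "Max nucleophilic reactivity index for C atoms" }
        ],
        "abc_pred_r2": [0.729, 0.756, 0.689],
        "abc_avg_printed": 0.725
      }
    }
  }
}
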