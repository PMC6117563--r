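{
  "comment": "Fitted rate constants for the tetrameric GluN1/GluN2A gating schemes. Units s^-1 except kp_a (M^-1 s^-1). 'gateway2' = two open gateways (openings from 3- and 4-subunit-gated states); 'allfour' = openings only after all four pre-gating steps.",
  "table3": {
    "nondesens": {
      "composite": {"k12": 568, "k21": 17700, "alpha1": 525, "beta1": 4580,
                    "alpha2": 8730, "beta2": 1580, "kp_f": 5000, "km_f": 2500,
                    "kp_s": 11.1, "km_s": 8.56},
      "mean": {"k12": 1170, "k21": 16400, "alpha1": 428, "beta1": 4390,
               "alpha2": 8080, "beta2": 2350, "kp_f": 4940, "km_f": 2630,
               "kp_s": 14.0, "km_s": 9.31}
    },
    "desens": {
      "composite": {"k12": 1390, "k21": 15200, "alpha1": 344, "beta1": 4130,
                    "alpha2": 5670, "beta2": 3550, "kp_f": 4580, "km_f": 2500,
                    "kp_s": 256, "km_s": 225, "kp_d": 5.28, "km_d": 1.78},
      "mean": {"k12": 2330, "k21": 12900, "alpha1": 250, "beta1": 3300,
               "alpha2": 4830, "beta2": 4840, "kp_f": 5470, "km_f": 3420,
               "kp_s": 236, "km_s": 230, "kp_d": 4.57, "km_d": 2.34}
    }
  },
  "tableA1": {
    "gateway2": {
      "single_channel": {"k12": 1390, "k21": 15200, "alpha1": 344, "beta1": 4130,
                         "alpha2": 5670, "beta2": 3550, "kp_f": 4580, "km_f": 2500,
                         "kp_s": 256, "km_s": 225, "kp_d": 5.28, "km_d": 1.78},
      "macroscopic": {"k12": 1390, "k21": 15200, "alpha1": 344, "beta1": 4130,
                      "alpha2": 5670, "beta2": 3550, "kp_f": 4580, "km_f": 2500,
                      "kp_s": 256, "km_s": 225, "kp_d": 7.41, "km_d": 1.54,
                      "kp_a": 6.7e6, "km_a": 65}
    },
    "allfour": {
      "single_channel": {"k12": 15000, "k21": 4110, "alpha1": 3700, "beta1": 4010,
                         "kp_f": 4880, "km_f": 2730, "kp_s": 572, "km_s": 87.3,
                         "kp_d": 3.32, "km_d": 1.81},
      "macroscopic": {"k12": 15000, "k21": 4110, "alpha1": 3700, "beta1": 4010,
                      "kp_f": 4880, "km_f": 2730, "kp_s": 572, "km_s": 87.3,
                      "kp_d": 4.63, "km_d": 1.60, "kp_a": 1.3e7, "km_a": 483}
    }
  }
}
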