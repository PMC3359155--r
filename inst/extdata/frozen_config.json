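{
  "params": {
    "k1": 0.085,
    "k2": 0.143,
    "k3": 500,
    "k4": 0.0012,
    "k5": 0.0072,
    "k55": 20,
    "k6": 0.962,
    "k7": 0.012,
    "k8": 0.08,
    "k88": 10,
    "k9": 0.08,
    "k10": 0.001,
    "k1010": 0.8,
    "lambda1": 0.0001,
    "lambda2": 0.0001,
    "P": 0.01,
    "T": 0.300523972100156,
    "YT": 50,
    "U_basal": 1e-06,
    "Xbasal": 0.0001,
    "XPbasal": 0
  },
  "U_stim": 10,
  "prime_margin": 2,
  "report": {
    "targets": {
      "upper": 95,
      "unstable": 9.4
    },
    "achieved": {
      "upper": 95.0000000000055,
      "unstable": 9.4552930177197
    },
    "relative_residuals": {
      "upper": 5.81897103601429e-14,
      "unstable": 0.00588223592762711
    },
    "P": 0.01,
    "T": 0.300523972100156,
    "YT": 50,
    "U_basal": 1e-06,
    "method": "deterministic least squares: T solved by 1-D root so the upper stable quartic root matches its target at each P; P chosen in [0.01, 100] uM minimizing the squared relative error of the unstable root; seed-free"
  }
}
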