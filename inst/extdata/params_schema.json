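{
  "title": "cpebswitch parameter set",
  "description": "All fields are required; unknown fields are rejected. Concentrations in uM, first-order rates in 1/s, second-order rates in 1/(uM s).",
  "fields": {
    "k1":      {"unit": "1/(uM s)", "role": "X + XP association into the autophosphorylation complex C1"},
    "k2":      {"unit": "1/s",      "role": "C1 dissociation"},
    "k3":      {"unit": "1/s",      "role": "C1 -> 2 XP autophosphorylation catalysis (500 for condition I, 0.5 for condition II)"},
    "k4":      {"unit": "1/(uM s)", "role": "XP dephosphorylation by the phosphatase"},
    "k5":      {"unit": "1/(uM s)", "role": "CPEB1 + XP association into C2"},
    "k55":     {"unit": "1/s",      "role": "C2 dissociation"},
    "k6":      {"unit": "1/s",      "role": "C2 -> YP + XP CPEB1 phosphorylation catalysis"},
    "k7":      {"unit": "1/(uM s)", "role": "YP dephosphorylation by the phosphatase"},
    "k8":      {"unit": "1/(uM s)", "role": "YP + T association into the translation complex C3"},
    "k88":     {"unit": "1/s",      "role": "C3 dissociation"},
    "k9":      {"unit": "1/s",      "role": "C3 -> YP + X + T synthesis catalysis"},
    "k10":     {"unit": "1/(uM s)", "role": "Ca4CaM activation of X"},
    "k1010":   {"unit": "1/s",      "role": "reverse of the Ca4CaM activation"},
    "lambda1": {"unit": "1/s",      "role": "degradation/relaxation acting on free XP"},
    "lambda2": {"unit": "1/s",      "role": "degradation/relaxation acting on free X"},
    "P":       {"unit": "uM",       "role": "phosphatase concentration (calibrated)"},
    "T":       {"unit": "uM",       "role": "translation-machinery concentration (calibrated)"},
    "YT":      {"unit": "uM",       "role": "total CPEB1 concentration (frozen)"},
    "U_basal": {"unit": "uM",       "role": "resting Ca4CaM concentration"},
    "Xbasal":  {"unit": "uM",       "role": "basal inactive alphaCaMKII"},
    "XPbasal": {"unit": "uM",       "role": "basal phospho-alphaCaMKII"}
  }
}
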