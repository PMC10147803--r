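{
  "version": 2,
  "comment": "Synthetic per-etiology cohort mixture parameters. Index order: age (years), cobb_major (deg), kyphosis (deg), levels_cobb, levels_kyphosis. Values are plausible clinical magnitudes chosen within valid ranges (age 0.5-10 y, Cobb 15-140 deg, kyphosis 5-120 deg, levels 3-14); they are synthetic design points for well-separated three-component cohorts and do not reproduce any registry cohort. Components are ordered by ascending mean Cobb; neuromuscular and syndromic each carry one kyphosis-dominant component (mean kyphosis > mean Cobb, expected deformity index < 1); idiopathic carries a severe-kyphotic component whose deformity index nevertheless stays above 1.",
  "etiologies": {
    "congenital": {
      "clusters": [
        {"weight": 0.34, "mean": [1.5, 35, 27, 4, 5], "sd": [0.5, 5, 5, 0.8, 0.8]},
        {"weight": 0.33, "mean": [5.0, 65, 38, 8, 9], "sd": [0.5, 5, 5, 0.8, 0.8]},
        {"weight": 0.33, "mean": [8.5, 95, 45, 12, 13], "sd": [0.5, 5, 5, 0.8, 0.8]}
      ]
    },
    "idiopathic": {
      "clusters": [
        {"weight": 0.34, "mean": [1.5, 32, 24, 4, 5], "sd": [0.5, 5, 4, 0.8, 0.8]},
        {"weight": 0.33, "mean": [5.0, 70, 28, 8, 9], "sd": [0.5, 5, 4, 0.8, 0.8]},
        {"weight": 0.33, "mean": [8.5, 95, 80, 12, 13], "sd": [0.5, 5, 4, 0.8, 0.8]}
      ]
    },
    "neuromuscular": {
      "clusters": [
        {"weight": 0.34, "mean": [2.0, 38, 68, 4, 9], "sd": [0.5, 5, 5, 0.8, 0.8]},
        {"weight": 0.33, "mean": [5.5, 70, 42, 8, 5], "sd": [0.5, 5, 5, 0.8, 0.8]},
        {"weight": 0.33, "mean": [9.0, 108, 62, 12, 13], "sd": [0.5, 5, 5, 0.8, 0.8]}
      ]
    },
    "syndromic": {
      "clusters": [
        {"weight": 0.34, "mean": [2.5, 36, 62, 4, 9], "sd": [0.5, 5, 5, 0.8, 0.8]},
        {"weight": 0.33, "mean": [6.0, 66, 40, 8, 5], "sd": [0.5, 5, 5, 0.8, 0.8]},
        {"weight": 0.33, "mean": [9.0, 98, 55, 12, 13], "sd": [0.5, 5, 5, 0.8, 0.8]}
      ]
    }
  }
}
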