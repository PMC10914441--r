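{
  "symmetric": [
    "ventral_diencephalon", "pallidum", "putamen", "caudate", "accumbens",
    "amygdala", "thalamus", "hippocampus", "supp_motor_cortex",
    "frontal_pole", "precentral_gyrus", "operculum", "gyrus_rectus",
    "occipital_pole"
  ],
  "midline": ["brainstem", "cerebellum_gm", "vermis_I_V", "vermis_VI_VII",
              "vermis_VIII_X"],
  "groups": {
    "striatum": ["putamen", "caudate", "accumbens"],
    "frontal_cortex": ["supp_motor_cortex", "frontal_pole",
                       "precentral_gyrus", "operculum", "gyrus_rectus"],
    "vermis": ["vermis_I_V", "vermis_VI_VII", "vermis_VIII_X"]
  }
}
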