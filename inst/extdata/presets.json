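{
  "comment": "Neural-mass parameter presets. Units: W in mV, tau_w in s, C dimensionless coupling, noise mean in spikes/s and noise sd in spikes/s/sqrt(Hz) (white-noise intensity). Non-background cortical presets are multiplicative deltas on background; they were calibrated once against the package's own regime tests and then frozen.",
  "cortical": {
    "background": {
      "sigmoid": {
        "PYR": {
          "e0": 2.5,
          "r": 0.56,
          "v0": 6
        },
        "PYR2": {
          "e0": 2.5,
          "r": 0.56,
          "v0": 6
        },
        "PV": {
          "e0": 2.5,
          "r": 0.56,
          "v0": 6
        },
        "SST": {
          "e0": 2.5,
          "r": 0.56,
          "v0": 6
        },
        "VIP": {
          "e0": 2.5,
          "r": 0.56,
          "v0": 6
        },
        "NGFC": {
          "e0": 2.5,
          "r": 0.56,
          "v0": 6
        }
      },
      "synapses": {
        "pyr_pyr2": {
          "W": 3.25,
          "tau_w": 0.01,
          "C": 135
        },
        "pyr2_pyr": {
          "W": 3.25,
          "tau_w": 0.01,
          "C": 108
        },
        "pyr_pv": {
          "W": 3.25,
          "tau_w": 0.01,
          "C": 33.75
        },
        "pyr_sst": {
          "W": 3.25,
          "tau_w": 0.01,
          "C": 33.75
        },
        "pv_pyr": {
          "W": 22.0,
          "tau_w": 0.005,
          "C": 5
        },
        "sst_pyr_apical": {
          "W": 10.0,
          "tau_w": 0.02,
          "C": 50
        },
        "sst_pyr_basal": {
          "W": 10.0,
          "tau_w": 0.012,
          "C": 40
        },
        "sst_pv": {
          "W": 10.0,
          "tau_w": 0.02,
          "C": 3
        },
        "vip_sst": {
          "W": 10.0,
          "tau_w": 0.015,
          "C": 10
        },
        "ngfc_pyr": {
          "W": 8.0,
          "tau_w": 0.06,
          "C": 5
        },
        "pyr_ngfc": {
          "W": 3.25,
          "tau_w": 0.01,
          "C": 10
        },
        "noise_pyr": {
          "W": 3.25,
          "tau_w": 0.01,
          "C": 1
        },
        "lr_pyr": {
          "W": 3.25,
          "tau_w": 0.01,
          "C": 1
        },
        "lr_pv": {
          "W": 3.25,
          "tau_w": 0.01,
          "C": 1
        },
        "lr_sst": {
          "W": 3.25,
          "tau_w": 0.01,
          "C": 1
        },
        "lr_vip": {
          "W": 3.25,
          "tau_w": 0.01,
          "C": 1
        },
        "lr_ngfc": {
          "W": 3.25,
          "tau_w": 0.01,
          "C": 1
        }
      },
      "noise": {
        "mean": 90,
        "sd": 5
      }
    },
    "fcd_spikewave": {
      "comment": "raised glutamatergic and PV-somatic gain, strongly reduced SST dendritic gain; slow volume-inhibition loop and drive coupling fine-tuned so the 2-3 Hz spike-wave regime holds",
      "deltas": {
        "pyr_pyr2": {
          "W": 1.9
        },
        "pyr2_pyr": {
          "W": 1.9
        },
        "pv_pyr": {
          "W": 1.3
        },
        "sst_pyr_apical": {
          "W": 0.25
        },
        "sst_pyr_basal": {
          "W": 0.25
        },
        "ngfc_pyr": {
          "C": 9
        },
        "pyr_ngfc": {
          "C": 4.5
        },
        "noise_pyr": {
          "C": 2.4
        }
      }
    },
    "alpha_boost": {
      "comment": "raised SST dendritic inhibition; drive coupling raised to stand in for the network afferents an occipital column receives in situ",
      "deltas": {
        "sst_pyr_apical": {
          "W": 1.3
        },
        "sst_pyr_basal": {
          "W": 1.3
        }
      },
      "noise": {
        "mean": 220,
        "sd": 5
      }
    },
    "beta_boost": {
      "comment": "raised PV somatic inhibition (gain and coupling); same drive stand-in",
      "deltas": {
        "pv_pyr": {
          "W": 2.2,
          "C": 4.0
        }
      },
      "noise": {
        "mean": 220,
        "sd": 5
      }
    },
    "delta_boost": {
      "comment": "slowed PSP kinetics in the main loops",
      "deltas": {
        "pyr_pyr2": {
          "tau_w": 2.0
        },
        "pyr2_pyr": {
          "tau_w": 2.0
        },
        "pyr_pv": {
          "tau_w": 2.0
        },
        "pyr_sst": {
          "tau_w": 2.0
        },
        "pv_pyr": {
          "tau_w": 2.0
        },
        "sst_pyr_apical": {
          "tau_w": 2.0
        },
        "sst_pyr_basal": {
          "tau_w": 2.0
        }
      },
      "noise": {
        "mean": 220,
        "sd": 5
      }
    }
  },
  "thalamus": {
    "sigmoid": {
      "TC": {
        "e0": 2.5,
        "r": 0.56,
        "v0": 6
      },
      "RN1": {
        "e0": 2.5,
        "r": 0.56,
        "v0": 6
      },
      "RN2": {
        "e0": 2.5,
        "r": 0.56,
        "v0": 6
      }
    },
    "synapses": {
      "ctx_tc": {
        "W": 3.25,
        "tau_w": 0.01,
        "C": 15
      },
      "ctx_rn1": {
        "W": 3.25,
        "tau_w": 0.01,
        "C": 10
      },
      "ctx_rn2": {
        "W": 3.25,
        "tau_w": 0.01,
        "C": 10
      },
      "tc_rn1": {
        "W": 3.25,
        "tau_w": 0.01,
        "C": 15
      },
      "tc_rn2": {
        "W": 3.25,
        "tau_w": 0.01,
        "C": 15
      },
      "rn1_tc": {
        "W": 10.0,
        "tau_w": 0.03,
        "C": 15
      },
      "rn2_tc": {
        "W": 22.0,
        "tau_w": 0.005,
        "C": 15
      },
      "noise_tc": {
        "W": 3.25,
        "tau_w": 0.01,
        "C": 1
      }
    },
    "noise": {
      "mean": 60,
      "sd": 20
    }
  }
}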