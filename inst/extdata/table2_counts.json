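{
  "comment": "Published confusion counts (TP/FP/FN/TN), operating cutoffs and printed integer-percent metric cells of the diagnostic-performance comparison table: combined model, CNN model, FIB-4, APRI and two radiologists on the three testing datasets.",
  "internal1": {
    "n": 94,
    "combined":     {"tp": 60, "fp": 5,  "fn": 7,  "tn": 22, "cutoff": 0.53405,
                     "printed": {"sensitivity": 90, "specificity": 81, "ppv": 92, "npv": 76, "accuracy": 87}},
    "cnn":          {"tp": 58, "fp": 7,  "fn": 9,  "tn": 20, "cutoff": 0.54343,
                     "printed": {"sensitivity": 87, "specificity": 74, "ppv": 89, "npv": 69, "accuracy": 83}},
    "fib4":         {"tp": 46, "fp": 9,  "fn": 21, "tn": 18, "cutoff": 2.26352,
                     "printed": {"sensitivity": 69, "specificity": 67, "ppv": 84, "npv": 46, "accuracy": 68}},
    "apri":         {"tp": 48, "fp": 10, "fn": 19, "tn": 17, "cutoff": 0.54094,
                     "printed": {"sensitivity": 72, "specificity": 63, "ppv": 83, "npv": 47, "accuracy": 69}},
    "radiologist1": {"tp": 55, "fp": 9,  "fn": 12, "tn": 18,
                     "printed": {"sensitivity": 82, "specificity": 67, "ppv": 86, "npv": 60, "accuracy": 78}},
    "radiologist2": {"tp": 48, "fp": 4,  "fn": 19, "tn": 23,
                     "printed": {"sensitivity": 72, "specificity": 85, "ppv": 92, "npv": 55, "accuracy": 76}}
  },
  "internal2": {
    "n": 266,
    "combined":     {"tp": 156, "fp": 25, "fn": 24, "tn": 61, "cutoff": 0.53405,
                     "printed": {"sensitivity": 87, "specificity": 71, "ppv": 86, "npv": 72, "accuracy": 82}},
    "cnn":          {"tp": 146, "fp": 18, "fn": 34, "tn": 68, "cutoff": 0.54343,
                     "printed": {"sensitivity": 81, "specificity": 79, "ppv": 89, "npv": 67, "accuracy": 80}},
    "fib4":         {"tp": 115, "fp": 31, "fn": 65, "tn": 55, "cutoff": 2.26352,
                     "printed": {"sensitivity": 64, "specificity": 64, "ppv": 79, "npv": 46, "accuracy": 64}},
    "apri":         {"tp": 107, "fp": 33, "fn": 73, "tn": 53, "cutoff": 0.54094,
                     "printed": {"sensitivity": 59, "specificity": 62, "ppv": 76, "npv": 42, "accuracy": 60}},
    "radiologist1": {"tp": 134, "fp": 23, "fn": 46, "tn": 63,
                     "printed": {"sensitivity": 74, "specificity": 73, "ppv": 85, "npv": 58, "accuracy": 74}},
    "radiologist2": {"tp": 128, "fp": 8,  "fn": 52, "tn": 78,
                     "printed": {"sensitivity": 71, "specificity": 91, "ppv": 94, "npv": 60, "accuracy": 77}}
  },
  "external": {
    "n": 115,
    "combined":     {"tp": 62, "fp": 11, "fn": 12, "tn": 30, "cutoff": 0.58556,
                     "printed": {"sensitivity": 84, "specificity": 73, "ppv": 85, "npv": 71, "accuracy": 80}},
    "cnn":          {"tp": 57, "fp": 13, "fn": 17, "tn": 28, "cutoff": 0.57295,
                     "printed": {"sensitivity": 77, "specificity": 68, "ppv": 81, "npv": 62, "accuracy": 74}},
    "fib4":         {"tp": 46, "fp": 14, "fn": 28, "tn": 27, "cutoff": 3.03248,
                     "printed": {"sensitivity": 62, "specificity": 66, "ppv": 77, "npv": 49, "accuracy": 63}},
    "apri":         {"tp": 48, "fp": 19, "fn": 26, "tn": 22, "cutoff": 1.03125,
                     "printed": {"sensitivity": 65, "specificity": 54, "ppv": 72, "npv": 46, "accuracy": 61}},
    "radiologist1": {"tp": 54, "fp": 11, "fn": 20, "tn": 30,
                     "printed": {"sensitivity": 73, "specificity": 73, "ppv": 83, "npv": 60, "accuracy": 73}},
    "radiologist2": {"tp": 52, "fp": 12, "fn": 22, "tn": 29,
                     "printed": {"sensitivity": 70, "specificity": 71, "ppv": 81, "npv": 57, "accuracy": 70}}
  }
}
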