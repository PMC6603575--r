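{
  "classes": ["on_bed", "off_bed", "lying"],
  "note": "Published 5-fold cross-validation confusion matrices (rows = actual, columns = predicted) and the published per-class / overall F-scores (percent, macro average) for each modality and classifier.",
  "smartphone": {
    "rf": {
      "matrix": [[180, 2, 34], [0, 1737, 1], [33, 1, 262]],
      "printed_f": {"on_bed": 83.9, "off_bed": 99.9, "lying": 88.4, "overall": 90.7}
    },
    "svm": {
      "matrix": [[170, 0, 46], [0, 1738, 0], [22, 1, 273]],
      "printed_f": {"on_bed": 83.3, "off_bed": 100.0, "lying": 88.8, "overall": 90.7}
    },
    "wsvm": {
      "matrix": [[193, 0, 23], [0, 1738, 0], [24, 0, 272]],
      "printed_f": {"on_bed": 89.1, "off_bed": 100.0, "lying": 92.0, "overall": 93.7}
    }
  },
  "rfid": {
    "rf": {
      "matrix": [[312, 3, 8], [13, 20, 0], [4, 1, 1003]],
      "printed_f": {"on_bed": 95.7, "off_bed": 70.2, "lying": 99.4, "overall": 88.4}
    },
    "svm": {
      "matrix": [[311, 2, 10], [13, 19, 1], [8, 0, 1000]],
      "printed_f": {"on_bed": 95.0, "off_bed": 70.4, "lying": 99.1, "overall": 88.1}
    },
    "wsvm": {
      "matrix": [[303, 15, 5], [9, 24, 0], [12, 1, 995]],
      "printed_f": {"on_bed": 93.7, "off_bed": 65.8, "lying": 99.1, "overall": 86.2}
    }
  }
}
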