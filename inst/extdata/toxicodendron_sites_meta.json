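{
  "groups": {
    "west": ["NUJ", "YAN", "JUL", "QIC", "CHI", "KKS", "DSH", "LGS", "FJS",
             "BYS", "BDG", "YUN", "LIC", "XDS", "BDO", "MPX", "WUF", "CHE",
             "BPX", "XLS", "MEI", "FOP", "SHT", "SJZ", "ZHA", "BXZ", "LUS",
             "LUC", "YUT", "JIK", "XIA", "LIS", "LKS", "WUA", "QBG", "ZSY",
             "ZAN"],
    "east": ["AHH", "ZAO", "SZB", "YTS", "KYS", "BEN", "HUA", "TSS", "JIA",
             "ZHZ", "OKC", "WNJ", "SED", "HIT", "TKD", "BGO", "TNO", "TSY",
             "OTY", "BCU", "NIM", "YSR", "YKN", "NYN", "SNI", "MSG", "SKW",
             "HID", "WJM", "SZU", "MNM", "KKR", "OGN", "AZW", "DIG", "OWN",
             "AMS", "SNG", "SDI", "JBJ", "INH", "ABS"]
  },
  "haplotype_order": ["H1", "H2", "H3", "H4", "H5"],
  "step_distances": {
    "comment": "pairwise mutational steps implied by the published median-joining network (path H2-1-H1-3-H4-2-H3-1-H5)",
    "labels": ["H1", "H2", "H3", "H4", "H5"],
    "matrix": [[0, 1, 5, 3, 6],
               [1, 0, 6, 4, 7],
               [5, 6, 0, 2, 1],
               [3, 4, 2, 0, 3],
               [6, 7, 1, 3, 0]]
  },
  "alignment_length_bp": 717,
  "presets": {
    "paper_permut_sites": {
      "comment": "published 47-site / 353-tree Permut dataset: Chinese cultivated trees excluded, Chinese sites with <3 wild trees dropped, Japanese sites combined within 0.625-degree grids as published. Membership realizes the published counts (39+1+7 sites, 327+4+22 trees); all Japanese/Korean sites are fixed for one haplotype, so the differentiation statistics are invariant to the particular Japanese pairing.",
      "china_excluded": ["LIC", "BDO", "WUA", "ZAN"],
      "japan_combined": {
        "SED_HIT": ["SED", "HIT"],
        "BCU_NIM": ["BCU", "NIM"],
        "SKW_HID": ["SKW", "HID"],
        "WJM_SZU": ["WJM", "SZU"],
        "OGN_AZW": ["OGN", "AZW"]
      },
      "japan_kept_single": ["TKD", "INH"],
      "korea_kept": ["OKC"]
    },
    "paper_amova_sites": {
      "comment": "published 75-site / 385-tree dataset: Chinese cultivated trees removed, cultivated-only Chinese sites dropped; derivable from the table by exclude_china_cultivated().",
      "china_cultivated_only_sites": ["YAN", "JUL", "JIA", "ZHZ"]
    },
    "table1_as_printed": {
      "comment": "per-site diversity statistics as printed include the cultivated trees of site ZAO (wild-only elsewhere).",
      "sites_with_cultivated_included": ["ZAO"]
    }
  }
}
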