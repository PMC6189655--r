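{
  "feature_id": "moderate_texture",
  "r_initial": 0.094799999999999995,
  "threshold": 0.59999999999999998,
  "n_raters": 50,
  "r_final": 0.63329999999999997,
  "converged": true,
  "rounds": [
    {
      "round_index": 1,
      "identified_raters": [
        "rater 45",
        "rater 49",
        "rater 32",
        "rater 42",
        "rater 34",
        "rater 40"
      ],
      "n_remaining": 44,
      "r_after": 0.16739999999999999
    },
    {
      "round_index": 2,
      "identified_raters": [
        "rater 20",
        "rater 16",
        "rater 13",
        "rater 3"
      ],
      "n_remaining": 40,
      "r_after": 0.222
    },
    {
      "round_index": 3,
      "identified_raters": [
        "rater 5",
        "rater 43"
      ],
      "n_remaining": 38,
      "r_after": 0.247
    },
    {
      "round_index": 4,
      "identified_raters": [
        "rater 15",
        "rater 25"
      ],
      "n_remaining": 36,
      "r_after": 0.2707
    },
    {
      "round_index": 5,
      "identified_raters": [
        "rater 29",
        "rater 39",
        "rater 33",
        "rater 47"
      ],
      "n_remaining": 32,
      "r_after": 0.32469999999999999
    },
    {
      "round_index": 6,
      "identified_raters": [
        "rater 31",
        "rater 35",
        "rater 50",
        "rater 26",
        "rater 38"
      ],
      "n_remaining": 27,
      "r_after": 0.4098
    },
    {
      "round_index": 7,
      "identified_raters": [
        "rater 41",
        "rater 17",
        "rater 1",
        "rater 10"
      ],
      "n_remaining": 23,
      "r_after": 0.48899999999999999
    },
    {
      "round_index": 8,
      "identified_raters": [
        "rater 46",
        "rater 19",
        "rater 44",
        "rater 37",
        "rater 30",
        "rater 18",
        "rater 11"
      ],
      "n_remaining": 16,
      "r_after": 0.63329999999999997
    }
  ]
}
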