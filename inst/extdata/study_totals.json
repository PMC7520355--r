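{
  "enrolled": 703103,
  "eligible_screened": 701301,
  "figure_caption_total": 703301,
  "unsatisfactory": 23157,
  "referred_abnormal": 34738,
  "ai_normal_sampled": 63811,
  "colposcopy_attended": 15494,
  "biopsied": 6697,
  "paired_total": 98549,
  "accuracy_set_total": 69906,
  "pair_row_totals": [63811, 23933, 1431, 8438, 936],
  "pair_col_totals": [65802, 22281, 1799, 7433, 1234],
  "histology_totals": [4790, 819, 279, 727, 82],
  "age_group_counts": {"20-29": 30035, "30-39": 113970, "40-49": 253474, "50-59": 235684, "60+": 69940},
  "notes": [
    "Three programme totals circulate in the source report: 703103 women enrolled, 701301 eligible women screened, and 703301 quoted in a figure caption; they are shipped as-is rather than reconciled.",
    "The concordant-normal component is 63209 (accuracy-set footnote), not the 63233 concordant-NILM cell of the paired table; the 24-woman gap is surfaced, not silently reconciled.",
    "Prevalence of AI-graded ASC-US is quoted against the enrolled total (23933/703103 = 3.4%)."
  ]
}
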