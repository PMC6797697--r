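# ASCO 2006 acute-phase antiemetic prophylaxis recommendations, encoded as
# admissible antiemetic class sets per (emetic risk category, age stratum).
# Each entry is a list of admissible sets; a regimen is concordant when it
# equals one of them exactly.
version: asco2006
recommendation:
  high:
    adult:
      - [NK1RA, 5HT3RA, steroid]
    under18:
      - [5HT3RA, steroid]
  moderate:
    adult:
      - [5HT3RA, steroid]
    under18:
      - [5HT3RA, steroid]
  low:
    adult:
      - [steroid]
    under18:
      - [steroid]
  minimal:
    adult:
      - []
    under18:
      - []
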