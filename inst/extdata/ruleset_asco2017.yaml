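# ASCO 2017 acute-phase antiemetic prophylaxis recommendations. Identical
# to the 2006 edition except: the pediatric (<18 y) high-risk recommendation
# adds the NK1RA, and the low-risk recommendation admits a 5HT3RA alone as
# an alternative to a steroid alone. For low risk the first listed set is
# the decomposition reference on ties (5HT3RA, the more prescribed option).
version: asco2017
recommendation:
  high:
    adult:
      - [NK1RA, 5HT3RA, steroid]
    under18:
      - [NK1RA, 5HT3RA, steroid]
  moderate:
    adult:
      - [5HT3RA, steroid]
    under18:
      - [5HT3RA, steroid]
  low:
    adult:
      - [5HT3RA]
      - [steroid]
    under18:
      - [5HT3RA]
      - [steroid]
  minimal:
    adult:
      - []
    under18:
      - []
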