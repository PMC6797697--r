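# Emetic risk map for chemotherapy drugs and class map for antiemetics.
# Edit to match the guideline edition in force at your site; categories are
# minimal / low / moderate / high. Dose-rule drugs are classified by
# administered dose divided by body surface area (mg per m2).
chemotherapy:
  cisplatin: high
  dacarbazine: high
  streptozocin: high
  carmustine: high
  mechlorethamine: high
  doxorubicin: moderate
  daunorubicin: moderate
  epirubicin: moderate
  idarubicin: moderate
  carboplatin: moderate
  oxaliplatin: moderate
  ifosfamide: moderate
  irinotecan: moderate
  azacitidine: moderate
  temozolomide: moderate
  etoposide: low
  methotrexate: low
  fluorouracil: low
  gemcitabine: low
  docetaxel: low
  paclitaxel: low
  topotecan: low
  mitoxantrone: low
  pemetrexed: low
  mercaptopurine: low
  vincristine: minimal
  vinblastine: minimal
  vinorelbine: minimal
  bleomycin: minimal
  fludarabine: minimal
  rituximab: minimal
  asparaginase: minimal
  nelarabine: minimal
dose_rules:
  cyclophosphamide:
    threshold_mg_per_m2: 1500
    boundary: at_or_above      # dose/BSA >= 1500 mg/m2
    category_high_side: high
    category_low_side: moderate
  cytarabine:
    threshold_mg_per_m2: 1000
    boundary: above            # dose/BSA > 1000 mg/m2
    category_high_side: moderate
    category_low_side: low
antiemetics:
  aprepitant: NK1RA
  fosaprepitant: NK1RA
  ondansetron: 5HT3RA
  granisetron: 5HT3RA
  ramosetron: 5HT3RA
  palonosetron: 5HT3RA
  azasetron: 5HT3RA
  dexamethasone: steroid
  prednisolone: steroid
  methylprednisolone: steroid
  betamethasone: steroid
  hydrocortisone: steroid
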