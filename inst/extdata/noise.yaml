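abbrev:
  by mouth:
  - po
  - PO
  once daily:
  - qd
  - every day
  twice daily:
  - bid
  three times daily:
  - tid
  four times daily:
  - qid
  at bedtime:
  - qhs
  - hs
  every other day:
  - qod
  as needed:
  - prn
  under the tongue:
  - sl
  subcutaneously:
  - subq
  every 4 hours:
  - q4h
  every 6 hours:
  - q6h
  tablet:
  - tab
  tablets:
  - tabs
  capsule:
  - cap
  capsules:
  - caps
  one:
  - '1'
  two:
  - '2'
  three:
  - '3'
  four:
  - '4'
typo_rate: 0.02
casing: keep

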