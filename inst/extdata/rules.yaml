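- id: abbr-po
  kind: literal
  match: po
  replace: by mouth
  word_boundary: yes
- id: abbr-qd
  kind: literal
  match: qd
  replace: once daily
  word_boundary: yes
- id: abbr-bid
  kind: literal
  match: bid
  replace: twice daily
  word_boundary: yes
- id: abbr-tid
  kind: literal
  match: tid
  replace: three times daily
  word_boundary: yes
- id: abbr-qid
  kind: literal
  match: qid
  replace: four times daily
  word_boundary: yes
- id: abbr-qod
  kind: literal
  match: qod
  replace: every other day
  word_boundary: yes
- id: abbr-qhs
  kind: literal
  match: qhs
  replace: at bedtime
  word_boundary: yes
- id: abbr-hs
  kind: literal
  match: hs
  replace: at bedtime
  word_boundary: yes
- id: abbr-prn
  kind: literal
  match: prn
  replace: as needed
  word_boundary: yes
- id: abbr-qam
  kind: literal
  match: qam
  replace: every morning
  word_boundary: yes
- id: abbr-qpm
  kind: literal
  match: qpm
  replace: every evening
  word_boundary: yes
- id: abbr-q4h
  kind: literal
  match: q4h
  replace: every 4 hours
  word_boundary: yes
- id: abbr-q6h
  kind: literal
  match: q6h
  replace: every 6 hours
  word_boundary: yes
- id: abbr-q8h
  kind: literal
  match: q8h
  replace: every 8 hours
  word_boundary: yes
- id: abbr-q12h
  kind: literal
  match: q12h
  replace: every 12 hours
  word_boundary: yes
- id: abbr-qday
  kind: literal
  match: q day
  replace: once daily
  word_boundary: yes
- id: abbr-everyday
  kind: literal
  match: every day
  replace: once daily
  word_boundary: yes
- id: abbr-tabs
  kind: literal
  match: tabs
  replace: tablets
  word_boundary: yes
- id: abbr-tab
  kind: literal
  match: tab
  replace: tablet
  word_boundary: yes
- id: abbr-caps
  kind: literal
  match: caps
  replace: capsules
  word_boundary: yes
- id: abbr-cap
  kind: literal
  match: cap
  replace: capsule
  word_boundary: yes
- id: abbr-sl
  kind: literal
  match: sl
  replace: under the tongue
  word_boundary: yes
- id: abbr-subq
  kind: literal
  match: subq
  replace: subcutaneously
  word_boundary: yes
- id: abbr-sq
  kind: literal
  match: sq
  replace: subcutaneously
  word_boundary: yes
- id: abbr-im
  kind: literal
  match: im
  replace: intramuscularly
  word_boundary: yes
- id: abbr-pr
  kind: literal
  match: pr
  replace: rectally
  word_boundary: yes
- id: abbr-pv
  kind: literal
  match: pv
  replace: vaginally
  word_boundary: yes
- id: abbr-ou
  kind: literal
  match: ou
  replace: in each eye
  word_boundary: yes
- id: abbr-au
  kind: literal
  match: au
  replace: in each ear
  word_boundary: yes
- id: abbr-gtts
  kind: literal
  match: gtts
  replace: drops
  word_boundary: yes
- id: abbr-gtt
  kind: literal
  match: gtt
  replace: drop
  word_boundary: yes
- id: abbr-ud
  kind: literal
  match: ud
  replace: as directed
  word_boundary: yes
- id: abbr-ac
  kind: literal
  match: ac
  replace: before meals
  word_boundary: yes
- id: abbr-pc
  kind: literal
  match: pc
  replace: after meals
  word_boundary: yes
- id: abbr-hrs
  kind: literal
  match: hrs
  replace: hours
  word_boundary: yes
- id: abbr-hr
  kind: literal
  match: hr
  replace: hour
  word_boundary: yes
- id: abbr-min
  kind: literal
  match: min
  replace: minutes
  word_boundary: yes
- id: num-1-unit
  kind: regex
  match: \b1\s+(tablet|capsule|puff|drop|patch|lozenge|spray|suppository|teaspoonful|applicatorful)\b
  replace: one \1
  word_boundary: no
- id: num-2-unit
  kind: regex
  match: \b2\s+(tablets|capsules|puffs|drops|patches|lozenges|sprays|suppositories|teaspoonfuls)\b
  replace: two \1
  word_boundary: no
- id: num-3-unit
  kind: regex
  match: \b3\s+(tablets|capsules|puffs|drops|patches|lozenges|sprays|suppositories|teaspoonfuls)\b
  replace: three \1
  word_boundary: no
- id: num-4-unit
  kind: regex
  match: \b4\s+(tablets|capsules|puffs|drops|patches|lozenges|sprays|suppositories|teaspoonfuls)\b
  replace: four \1
  word_boundary: no
- id: num-1-half
  kind: regex
  match: \b1 half\b
  replace: one half
  word_boundary: no
- id: freq-2xd
  kind: regex
  match: \b2 times daily\b
  replace: twice daily
  word_boundary: no
- id: freq-3xd
  kind: regex
  match: \b3 times daily\b
  replace: three times daily
  word_boundary: no
- id: freq-4xd
  kind: regex
  match: \b4 times daily\b
  replace: four times daily
  word_boundary: no
- id: freq-3xw
  kind: regex
  match: \b3 times weekly\b
  replace: three times weekly
  word_boundary: no
- id: dur-x-days
  kind: regex
  match: \bx\s*([0-9]+)\s*d(?:ays)?\b
  replace: for \1 days
  word_boundary: no
- id: unit-mgs
  kind: regex
  match: \b([0-9]+)\s*mgs\b
  replace: \1 mg
  word_boundary: no
- id: half
  kind: regex
  match: \b1/2\b
  replace: one half
  word_boundary: no

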