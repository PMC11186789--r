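[
  ["verb", "dose", "route", "frequency"],
  ["verb", "dose", "route", "frequency", "auxi-indic"],
  ["verb", "dose", "route", "frequency", "auxi-time"],
  ["verb", "dose", "route", "frequency", "auxi-period"],
  ["verb", "dose", "route", "frequency", "auxi-action"],
  ["verb", "dose", "route", "frequency", "auxi-maxdose"],
  ["verb", "dose", "route", "frequency", "auxi-indic", "auxi-period"],
  ["verb", "dose", "route", "frequency", "auxi-time", "auxi-action"],
  ["verb", "dose", "frequency"],
  ["verb", "dose", "frequency", "auxi-indic"],
  ["verb", "dose", "frequency", "auxi-time"],
  ["verb", "route", "frequency"],
  ["verb", "route", "frequency", "auxi-period"],
  ["verb", "dose", "route"],
  ["dose", "route", "frequency"],
  ["dose", "frequency"],
  ["verb", "dose", "route", "frequency", "auxi-indic", "auxi-time"],
  ["verb", "dose", "route", "frequency", "auxi-indic", "auxi-action"],
  ["verb", "dose", "route", "frequency", "auxi-indic", "auxi-maxdose"],
  ["verb", "dose", "route", "frequency", "auxi-period", "auxi-action"],
  ["verb", "dose", "frequency", "auxi-maxdose"],
  ["verb", "route", "frequency", "auxi-indic"],
  ["dose", "route", "frequency", "auxi-indic"],
  ["verb", "dose", "route", "frequency", "auxi-time", "auxi-period"]
]
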