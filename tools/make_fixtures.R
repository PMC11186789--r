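# Builds the fixture resources under inst/extdata/: component libraries,
# pattern library, normalization rules, medication catalog, noise model.
# Run from the repository root: Rscript tools/make_fixtures.R

suppressMessages(library(jsonlite))

# ---- component libraries ---------------------------------------------------

num_words <- c("one", "two", "three", "four")
num_digits <- c("1", "2", "3", "4")
count_units <- c("tablet", "capsule", "puff", "drop", "patch", "lozenge",
                 "spray", "suppository")
plural <- function(u) ifelse(u == "suppository", "suppositories", paste0(u, "s"))

dose_surfaces <- character(); dose_canon <- character()
for (u in count_units) {
  for (k in 1:4) {
    word_form <- if (k == 1) paste(num_words[k], u) else paste(num_words[k], plural(u))
    digit_form <- if (k == 1) paste(num_digits[k], u) else paste(num_digits[k], plural(u))
    dose_surfaces <- c(dose_surfaces, word_form, digit_form)
    dose_canon[digit_form] <- word_form
  }
}
dose_surfaces <- c(dose_surfaces,
  "one half tablet", "one and one half tablets",
  paste(c("2.5", "5", "10", "15", "20"), "ml"),
  paste(c("20", "25", "40", "50", "75", "100", "250", "500", "750", "1000"), "mg"),
  paste(c("10", "15", "20", "30", "40", "60"), "units"),
  "one teaspoonful", "two teaspoonfuls", "one applicatorful",
  "a thin layer", "a small amount", "one pea sized amount")

verbs <- c("take", "chew", "apply", "inhale", "inject", "instill", "insert",
           "use", "place", "spray", "dissolve", "swallow", "give")

routes <- c("by mouth", "under the tongue", "topically", "to the affected area",
            "in each eye", "in the right eye", "in the left eye",
            "in each ear", "in the right ear", "in the left ear",
            "in each nostril", "rectally", "vaginally", "subcutaneously",
            "intramuscularly", "by inhalation", "in the cheek")

freqs <- c("once daily", "twice daily", "three times daily",
           "four times daily", "every morning", "every evening",
           "at bedtime", "every 4 hours", "every 6 hours", "every 8 hours",
           "every 12 hours", "every other day", "once weekly", "twice weekly",
           "three times weekly", "once monthly", "every 2 weeks",
           "every 3 days", "as needed", "as directed", "daily", "weekly",
           "every night", "before each meal", "with each meal",
           "every 72 hours", "once daily as needed", "twice daily as needed",
           "every 4 to 6 hours", "up to three times daily")
freq_canon <- c("daily" = "once daily", "weekly" = "once weekly",
                "every night" = "at bedtime")

conditions <- c("pain", "anxiety", "depression", "high blood pressure",
  "cholesterol", "diabetes", "nausea", "vomiting", "fever", "inflammation",
  "swelling", "allergies", "insomnia", "sleep", "infection", "cough",
  "congestion", "heartburn", "acid reflux", "constipation", "diarrhea",
  "migraine", "headache", "seizures", "asthma", "breathing", "itching",
  "rash", "acne", "eczema", "dryness", "irritation", "muscle spasm",
  "cramps", "restless legs", "gout", "arthritis", "joint pain", "back pain",
  "nerve pain", "thyroid", "blood clots", "water retention", "mood",
  "attention", "smoking cessation", "blood sugar", "bladder spasms",
  "overactive bladder", "ulcers", "stomach upset", "dizziness",
  "cold sores", "dry eyes", "glaucoma", "ear wax", "motion sickness",
  "shortness of breath", "wheezing", "hot flashes")
auxi_indic <- paste("for", conditions)

auxi_time <- c("in the morning", "in the evening", "with breakfast",
               "with lunch", "with dinner", "with meals", "with food",
               "on an empty stomach", "before meals", "after meals",
               "30 minutes before breakfast", "at the same time each day",
               "before procedure", "before surgery", "one hour before meals",
               "at onset of symptoms")

auxi_period <- c("for 5 days", "for 7 days", "for 10 days", "for 14 days",
                 "for 21 days", "for 30 days", "for 90 days", "for 1 week",
                 "for 2 weeks", "for 12 weeks", "for 3 months",
                 "until finished", "until gone", "for the first week",
                 "then stop")

auxi_action <- c("do not crush", "swallow whole", "shake well before use",
                 "rinse mouth after use", "avoid sunlight",
                 "take with plenty of water", "apply sparingly",
                 "wash hands after use", "rotate application sites",
                 "do not drive", "may cause drowsiness", "protect from light",
                 "remove old patch first", "dissolve slowly in mouth",
                 "do not swallow")

# written in the normalizer's output dialect: counts of 1-4 before dose
# units appear as words, since the rules rewrite the digit forms
auxi_maxdose <- c("maximum four tablets daily", "maximum three tablets per day",
                  "maximum 6 tablets daily", "do not exceed 4 doses in 24 hours",
                  "do not exceed two tablets in 24 hours",
                  "no more than 8 tablets in 24 hours",
                  "no more than 4 doses daily", "maximum 4 grams per day",
                  "maximum two patches per day",
                  "do not exceed 12 puffs in 24 hours")

libs <- list(
  "verb" = verbs, "dose" = dose_surfaces, "route" = routes,
  "frequency" = freqs, "auxi-indic" = auxi_indic, "auxi-time" = auxi_time,
  "auxi-period" = auxi_period, "auxi-action" = auxi_action,
  "auxi-maxdose" = auxi_maxdose)
canon <- list("dose" = dose_canon, "frequency" = freq_canon)

# cross-label duplicate surfaces would make the dictionary tagger ambiguous
all_surf <- unlist(libs, use.names = FALSE)
stopifnot(!anyDuplicated(all_surf))

obj <- lapply(names(libs), function(lab) {
  s <- libs[[lab]]
  cm <- canon[[lab]]
  vals <- s
  if (!is.null(cm)) {
    hit <- match(s, names(cm))
    vals[!is.na(hit)] <- cm[hit[!is.na(hit)]]
  }
  as.list(setNames(vals, s))
})
names(obj) <- names(libs)
write_json(obj, "inst/extdata/libraries.json", auto_unbox = TRUE, pretty = TRUE)

# ---- pattern library -------------------------------------------------------

pats <- list(
  c("verb", "dose", "route", "frequency"),
  c("verb", "dose", "route", "frequency", "auxi-indic"),
  c("verb", "dose", "route", "frequency", "auxi-time"),
  c("verb", "dose", "route", "frequency", "auxi-period"),
  c("verb", "dose", "route", "frequency", "auxi-action"),
  c("verb", "dose", "route", "frequency", "auxi-maxdose"),
  c("verb", "dose", "route", "frequency", "auxi-indic", "auxi-period"),
  c("verb", "dose", "route", "frequency", "auxi-time", "auxi-action"),
  c("verb", "dose", "frequency"),
  c("verb", "dose", "frequency", "auxi-indic"),
  c("verb", "dose", "frequency", "auxi-time"),
  c("verb", "route", "frequency"),
  c("verb", "route", "frequency", "auxi-period"),
  c("verb", "dose", "route"),
  c("dose", "route", "frequency"),
  c("dose", "frequency"),
  c("verb", "dose", "route", "frequency", "auxi-indic", "auxi-time"),
  c("verb", "dose", "route", "frequency", "auxi-indic", "auxi-action"),
  c("verb", "dose", "route", "frequency", "auxi-indic", "auxi-maxdose"),
  c("verb", "dose", "route", "frequency", "auxi-period", "auxi-action"),
  c("verb", "dose", "frequency", "auxi-maxdose"),
  c("verb", "route", "frequency", "auxi-indic"),
  c("dose", "route", "frequency", "auxi-indic"),
  c("verb", "dose", "route", "frequency", "auxi-time", "auxi-period"))
write_json(pats, "inst/extdata/patterns.json", pretty = TRUE)

# ---- normalization rules ---------------------------------------------------

lit <- function(id, match, replace)
  list(id = id, kind = "literal", match = match, replace = replace,
       word_boundary = TRUE)
rgx <- function(id, match, replace)
  list(id = id, kind = "regex", match = match, replace = replace,
       word_boundary = FALSE)

rules <- list(
  lit("abbr-po", "po", "by mouth"),
  lit("abbr-qd", "qd", "once daily"),
  lit("abbr-bid", "bid", "twice daily"),
  lit("abbr-tid", "tid", "three times daily"),
  lit("abbr-qid", "qid", "four times daily"),
  lit("abbr-qod", "qod", "every other day"),
  lit("abbr-qhs", "qhs", "at bedtime"),
  lit("abbr-hs", "hs", "at bedtime"),
  lit("abbr-prn", "prn", "as needed"),
  lit("abbr-qam", "qam", "every morning"),
  lit("abbr-qpm", "qpm", "every evening"),
  lit("abbr-q4h", "q4h", "every 4 hours"),
  lit("abbr-q6h", "q6h", "every 6 hours"),
  lit("abbr-q8h", "q8h", "every 8 hours"),
  lit("abbr-q12h", "q12h", "every 12 hours"),
  lit("abbr-qday", "q day", "once daily"),
  lit("abbr-everyday", "every day", "once daily"),
  lit("abbr-tabs", "tabs", "tablets"),
  lit("abbr-tab", "tab", "tablet"),
  lit("abbr-caps", "caps", "capsules"),
  lit("abbr-cap", "cap", "capsule"),
  lit("abbr-sl", "sl", "under the tongue"),
  lit("abbr-subq", "subq", "subcutaneously"),
  lit("abbr-sq", "sq", "subcutaneously"),
  lit("abbr-im", "im", "intramuscularly"),
  lit("abbr-pr", "pr", "rectally"),
  lit("abbr-pv", "pv", "vaginally"),
  lit("abbr-ou", "ou", "in each eye"),
  lit("abbr-au", "au", "in each ear"),
  lit("abbr-gtts", "gtts", "drops"),
  lit("abbr-gtt", "gtt", "drop"),
  lit("abbr-ud", "ud", "as directed"),
  lit("abbr-ac", "ac", "before meals"),
  lit("abbr-pc", "pc", "after meals"),
  lit("abbr-hrs", "hrs", "hours"),
  lit("abbr-hr", "hr", "hour"),
  lit("abbr-min", "min", "minutes"),
  rgx("num-1-unit", "\\b1\\s+(tablet|capsule|puff|drop|patch|lozenge|spray|suppository|teaspoonful|applicatorful)\\b", "one \\1"),
  rgx("num-2-unit", "\\b2\\s+(tablets|capsules|puffs|drops|patches|lozenges|sprays|suppositories|teaspoonfuls)\\b", "two \\1"),
  rgx("num-3-unit", "\\b3\\s+(tablets|capsules|puffs|drops|patches|lozenges|sprays|suppositories|teaspoonfuls)\\b", "three \\1"),
  rgx("num-4-unit", "\\b4\\s+(tablets|capsules|puffs|drops|patches|lozenges|sprays|suppositories|teaspoonfuls)\\b", "four \\1"),
  rgx("num-1-half", "\\b1 half\\b", "one half"),
  rgx("freq-2xd", "\\b2 times daily\\b", "twice daily"),
  rgx("freq-3xd", "\\b3 times daily\\b", "three times daily"),
  rgx("freq-4xd", "\\b4 times daily\\b", "four times daily"),
  rgx("freq-3xw", "\\b3 times weekly\\b", "three times weekly"),
  rgx("dur-x-days", "\\bx\\s*([0-9]+)\\s*d(?:ays)?\\b", "for \\1 days"),
  rgx("unit-mgs", "\\b([0-9]+)\\s*mgs\\b", "\\1 mg"),
  rgx("half", "\\b1/2\\b", "one half"))

writeLines(yaml::as.yaml(rules), "inst/extdata/rules.yaml")

# ---- medication catalog ----------------------------------------------------

cat_rows <- list(
  c("D001", "lisinopril 10 mg oral tablet", "tablet", "10 mg", "lisinopril",
    "verb;dose;route;frequency", "take", "", "by mouth", "", ""),
  c("D002", "methotrexate 2.5 mg oral tablet", "tablet", "2.5 mg",
    "methotrexate", "verb;dose;route;frequency", "take", "", "by mouth", "", ""),
  c("D003", "amoxicillin 500 mg oral capsule", "capsule", "500 mg",
    "amoxicillin", "verb;dose;route;frequency", "take", "", "by mouth", "", ""),
  c("D004", "montelukast 4 mg chewable tablet", "tablet", "4 mg",
    "montelukast", "verb;dose;route;frequency", "chew", "", "by mouth", "", ""),
  c("D005", "hydrocortisone 1% topical cream", "cream", "1%",
    "hydrocortisone", "verb;route;frequency", "apply", "", "topically", "", ""),
  c("D006", "insulin glargine 100 units/ml pen-injector", "pen-injector",
    "100 units/ml", "insulin glargine", "verb;dose;route;frequency",
    "inject", "", "subcutaneously", "", ""),
  c("D007", "albuterol 90 mcg inhalation aerosol", "aerosol", "90 mcg",
    "albuterol", "verb;dose;route;frequency", "inhale", "", "by inhalation",
    "", ""),
  c("D008", "latanoprost 0.005% ophthalmic solution", "solution", "0.005%",
    "latanoprost", "verb;dose;route;frequency", "instill", "", "", "", ""),
  c("D009", "omeprazole 20 mg delayed-release capsule", "capsule", "20 mg",
    "omeprazole", "verb;dose;route;frequency", "take", "", "by mouth",
    "once daily", ""),
  c("D010", "ondansetron 4 mg oral tablet", "tablet", "4 mg", "ondansetron",
    "verb;dose;route;frequency", "take", "", "by mouth", "", "for nausea"))

header <- c("drug_id", "description", "dose_form", "strength",
            "active_ingredients", "required", "default_verb", "default_dose",
            "default_route", "default_frequency", "default_aux")
tsv <- c(paste(header, collapse = "\t"),
         vapply(cat_rows, paste, character(1), collapse = "\t"))
writeLines(tsv, "inst/extdata/catalog.tsv")

# ---- noise model -----------------------------------------------------------

noise <- list(
  abbrev = list(
    "by mouth" = list("po", "PO"),
    "once daily" = list("qd", "every day"),
    "twice daily" = list("bid"),
    "three times daily" = list("tid"),
    "four times daily" = list("qid"),
    "at bedtime" = list("qhs", "hs"),
    "every other day" = list("qod"),
    "as needed" = list("prn"),
    "under the tongue" = list("sl"),
    "subcutaneously" = list("subq"),
    "every 4 hours" = list("q4h"),
    "every 6 hours" = list("q6h"),
    "tablet" = list("tab"),
    "tablets" = list("tabs"),
    "capsule" = list("cap"),
    "capsules" = list("caps"),
    "one" = list("1"),
    "two" = list("2"),
    "three" = list("3"),
    "four" = list("4")),
  typo_rate = 0.02,
  casing = "keep")
writeLines(yaml::as.yaml(noise), "inst/extdata/noise.yaml")

cat("fixtures written\n")
for (f in list.files("inst/extdata", full.names = TRUE)) {
  cat(sprintf("  %-28s %6d bytes\n", f, file.size(f)))
}
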