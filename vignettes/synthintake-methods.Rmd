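---
title: "Methods: synthetic intake interviews and their evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic intake interviews and their evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`synthintake` simulates structured psychiatric intake interviews between two
chat agents and evaluates the output. This vignette documents the generative
model, the tunable parameters and their defaults, the numerical and design
choices that were genuinely open, and what the offline test results do and do
not establish.

## The patient model

A patient is the composition of independent draws from a population
configuration:

- **Marginals.** Ethnicity, age group, and sex are categorical draws. The
  exact age is uniform over the integers of the sampled bracket; the date of
  birth is then uniform over the days consistent with that exact age at the
  configuration's `reference_date` (fixed at 2025-01-01 in the packaged
  fixture), so age, bracket and date of birth are mutually consistent by
  construction.
- **Conditionals.** Relationship status is drawn from the (age bracket, sex)
  row of a conditional table over six categories (Single,
  Living-apart-together, Married, Common-law, Divorced/Separated, Widowed).
  Parental status (probability of at least one child) and disability
  prevalence are per-cell probabilities. A patient who draws a disability
  receives exactly one of ten configured types from the type-share
  distribution; multiple concurrent disability types are out of scope.
- **Clinical attributes.** With probability `prob_any` (fixture default 0.6)
  a patient receives 1–3 psychiatric conditions, the count drawn from weights
  (fixture default 0.6/0.3/0.1), conditions sampled without replacement, each
  paired with one medication from its catalog list. These defaults are
  deliberately arbitrary: the modelled quantity is a *range* (one to three
  comorbid conditions), and no reliable population distribution is available
  for the rate, so the fixture documents its own choice rather than implying
  a source.
- **Identity.** A name locale is drawn from configured locale weights and the
  name from that locale's packaged table; occupation and address come from
  packaged lists. These tables are synthetic stand-ins for an
  ethnicity-weighted name provider — every name and address is fabricated.
- **Narratives.** Each narrative field of the profile template is filled by
  the chat backend, grounded in the fixed fields.

The packaged population configuration is itself a documented placeholder: it
is structurally faithful to regional census-style tables (9 ethnicity
categories, 5 adult age groups, 2 sexes, the 6 relationship categories and 10
disability types above) with plausible urban south-western British Columbia
values, but it reproduces no official statistics. Regional re-targeting means
editing one JSON file; probabilities may carry `"normalize": true` because
census-derived percentages rarely sum exactly to 1 (otherwise sums are
enforced to 1 within 1e-9).

### Seeding

One master seed governs a cohort. Each patient uses a private RNG stream
seeded by a deterministic mix of `(master seed, patient index)`, so patient
*i* is byte-identical whether generated alone or in a batch, and cohorts of
different sizes share their common prefix. Derived seeds stay below 2^31.

## The interview engine

The interview alternates a patient agent and an interview-assistant agent.
The session starts with a hard-coded opener answered by the patient; the
assistant then works through a header-structured question bank (the packaged
bank has 5 sections and 47 points, ending with a closing point).

- **Roles.** Each agent sees the shared history relabelled from its own
  perspective: its turns as `assistant`, the counterpart's as `user`, with
  its own system prompt first. The packaged prompt texts implement a
  six-step loop for the assistant (identify previous question; note the
  latest answer as `Note: … <END_NOTE>`; assess completeness; clarify if
  needed; emit `RESPONSE: <STOP>` when done; otherwise acknowledge and ask
  the next point) and a five-step loop for the patient (identify the
  question; retrieve profile details; formulate; check clarity; deliver a
  single `RESPONSE:` line).
- **Chunking and dumping.** Only the current bank section is in the
  assistant's context; the next section is preloaded when a single
  undelivered point remains in the current one. Once a section completes and
  its closing answer is recorded, its turns leave the active window (they
  remain archived in the result) and are replaced by a summary of that
  section's notes truncated to 200 estimated tokens — the brief seeded
  summary convention. Token counts use a documented heuristic (whitespace
  tokens × 1.3, rounded up); the engine records the peak active-window
  estimate so the `num_ctx` bound is checkable per run.
- **Clarifications.** When the patient's answer is vague the assistant asks
  a clarification before advancing. The cap is configurable
  (`max_clarifications_per_point`, default 2): the assessment criteria are
  qualitative (clarity, detail, relevance) and no cap is prescribed anywhere,
  so the engine enforces a small finite budget to guarantee progress.
- **Termination.** The loop ends on a clean stop (payload exactly `<STOP>`
  after trimming — a stop token embedded in longer text is flagged, not
  honoured), on a backend error (partial transcript, `full_failure`), or at
  `max_turns`, defaulting to 4 × the number of bank points, which guarantees
  termination even under the `no_stop` fault.
- **Classification.** `full_failure`: no clean final stop, undelivered
  points, or an aborting error. `soft_failure`: any turn leaked reasoning
  around its `RESPONSE:` payload (extra text before the prefix beyond one
  well-formed note block, repeated prefixes, or a missing prefix).
  Otherwise `compliant`.

## Inference options

`temperature = 0.9`, `top_k = 40`, `top_p = 0.9`, `num_ctx = 6144` are the
defaults, a configuration that balances varied phrasing against prompt
adherence for locally served 70B-class chat models. They are forwarded verbatim to the backend; the
package implements no decoder. The scripted mock ignores them — its
variation comes from deterministic string hashing — which keeps every
offline path a pure function of `(messages, seed)`.

## The scripted mock backend

The mock exists so that the entire pipeline is testable without model
weights. It plays five tasks, recognized from tagged system-prompt blocks:
patient (keyword-matches the question against profile fields, with a
hash-deterministic vague-answer mode to exercise clarifications),
interview assistant (notes the last answer, asks the first listed point not
visible in its history, stops when none remain), profile-template
generation (one field per bank point; points naming sampler-owned
attributes become `fixed`, the rest `narrative`), narrative enrichment
(field-specific sentence patterns interpolating the fixed attributes), and
note summarization. Fault flags (`no_stop`, `premature_end`, `leak_cot`)
exist solely to exercise the failure taxonomy.

What the mock does *not* emulate: the lexical richness, empathy and
occasional disobedience of a real language model. Mock transcripts are
grammatical but repetitive, so their Distinct-1 values characterize the
mock, not any model; passing tests establish the correctness of sampling,
orchestration, protocol parsing, classification and metric code, and say
nothing about the linguistic quality of real-model output. Conversely, the
demographic machinery is exactly the production path — the calibration
results transfer to any backend because narrative text never feeds the
samplers.

## Evaluation conventions

- **Tokenizer.** Lowercase, punctuation stripped except apostrophes internal
  to a token, whitespace split. Published Distinct-1 figures depend on
  unstated tokenizer choices, so cross-study comparisons carry a tolerance of
  about ±0.03.
- **Duplicate Ratio.** "Appears identically more than once" is ambiguous
  between counting all occurrences of a repeated value and counting only the
  excess beyond the first. The default counts all occurrences (four
  identical segments give ratio 1.0); the excess rule is available via
  `rule = "excess"`.
- **Goodness of fit.** `chi2_gof` computes Σ(O−E)²/E with `df = k − 1`
  against configured probabilities; expected counts below 5 set a flag. The
  cohort report tests ethnicity, age group, and disability type — the latter
  among patients with any disability, against the type shares, since type is
  drawn independently of the (bracket, sex) cell given that a disability is
  present. The pooled relationship-status row uses expected probabilities
  mixed over the cohort's observed (bracket, sex) cells with `df = 5`; its
  expected counts include near-zero cells (Widowed in young brackets), so
  its chi-square approximation is slightly anticonservative at n = 1000 and
  it is reported as a descriptive row rather than included in the
  calibration suite, which covers the three rows above. The published
  relationship statistic pairs with a degrees-of-freedom convention that
  cannot be reconstructed unambiguously, so this report documents its own.
- **Parental comparison.** One-sided z-test of the pooled observed
  proportion against the cell-weighted expectation,
  `z = (p̂ − p₀)/√(p₀(1−p₀)/n)`, lower-tail p.
- **Inliers.** Directory-level medians are reported both over all
  stop-compliant sessions and over inliers (excluding full and soft
  failures). No multiple-testing correction is applied across fidelity rows.

## Problem sizes used by the test suite

The suite favours sizes that make binomial/multinomial oracles sharp while
keeping a default run short: 10⁵ draws for marginal calibration (three
binomial standard deviations per category), 500 seeded 1,000-patient cohorts
for the 5% ± 2% rejection-rate check of the three GOF rows, 100 seeded
end-to-end mock interviews on the 47-point bank, 50 seeds per fault flag on
a 6-point bank (the `no_stop` fault runs to the turn cap, so a compact bank
exercises the classification without inflating run time), 10⁴ random token
lists against brute-force metric oracles, and a 10⁴-patient profile
invariant sweep.

## Known limitations

- At most one disability type per patient; children's details are narrative
  (backend-filled), not sampled.
- No medication-safety or dosing validation; the condition–medication
  catalog is illustrative.
- The fixture's probabilities are placeholders; conclusions about any real
  region require substituting real tables.
- No hallucination, coherence or role-deviation checking beyond the
  protocol flags; semantic and clinical quality scoring is out of scope.
- The HTTP adapter forwards requests and surfaces errors; it cannot make a
  non-deterministic server reproducible.
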