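# synthintake

Synthetic psychiatric patients and structured intake interview transcripts,
with an evaluation suite for lexical diversity and demographic fidelity.

## The problem

Training and testing language-model tools for mental health needs realistic
interview data, but real psychiatric transcripts are locked behind privacy
law and consent constraints. `synthintake` generates the data synthetically:

1. **Patient profiles** are sampled from a population-statistics
   configuration — marginal categorical distributions (ethnicity, age group,
   sex, disability-type shares, name-locale weights), age-by-sex conditional
   tables (relationship status, parental status, disability prevalence) and
   an attribute catalog (psychiatric conditions with typical medications,
   0–3 comorbid conditions per affected patient). Free-text fields (family
   and social history, work history, daily lifestyle, ...) are filled by a
   chat backend.
2. **Interview transcripts** are produced by two chat agents — an interview
   assistant and the patient — alternating turns over a header-structured
   question bank. The bank is delivered in chunks: the next section is
   preloaded just before the current section's final question, and completed
   sections are dumped from active context and replaced by a brief note-based
   summary, so the active window never outgrows the configured `num_ctx`
   (6,144 tokens by default). The protocol is strict: every completion ends
   with a `RESPONSE:` payload, interviewer turns carry a
   `Note: … <END_NOTE>` digest, and the session ends when the interviewer
   emits a payload of exactly `<STOP>`. Sessions are classified `compliant`,
   `soft_failure` (leaked step-by-step reasoning) or `full_failure` (no clean
   stop, undelivered questions, or a backend error).
3. **Evaluation** covers per-role lexical diversity and cohort-level
   demographic fidelity.

All model calls go through one `chat(backend, messages, options)` contract.
A deterministic scripted mock plays every role offline (with fault-injection
hooks for the failure taxonomy), and an HTTP adapter targets any
Ollama-compatible server (`temperature = 0.9`, `top_k = 40`, `top_p = 0.9`,
`num_ctx = 6144` are forwarded, not implemented).

## The metrics

For a token sequence with `U` unique unigrams among `N` total:

    Distinct-1 = U / N

computed per transcript and per role (stop turn excluded). For a collection
of `N_tot` generated segments of which `N_dup` occur identically more than
once:

    Duplicate Ratio = N_dup / N_tot

Cohort fidelity uses the chi-square goodness of fit,
`χ² = Σ (O − E)² / E` with `E = p · n` and `df = k − 1`, for ethnicity, age
group and disability type (plus a pooled relationship-status row), and a
one-sided z-test of the pooled parental proportion against its cell-weighted
expectation.

## Worked example

```r
library(synthintake)
cfg  <- load_population_config(default_population_config_path())
bank <- read_question_bank(default_question_bank_path())
tpl  <- canonical_profile_template()

patient <- generate_patient(cfg, tpl, mock_backend(seed = 1),
                            master_seed = 42, index = 1)
patient
#> <patient_profile> patient_000001: Yan Huang, 55y female, Indigenous
#>   conditions: Bipolar II disorder
#>   narrative fields: 35

res <- run_interview(patient, bank, mock_backend(seed = 5),
                     mock_backend(seed = 6), seed = 5)
res
#> <interview_result> patient_000001_s5 | status: compliant | 96 turns, 47 notes
#>   points delivered: 47 (0 undelivered) | peak context ~2103 tokens

co <- lapply(1:1000, function(i) {
  rng <- rng_stream(derive_stream_seed(7, i))
  b <- sample_demographics(cfg, rng)
  b$disabilities <- assign_disability(b, cfg, rng)
  b
})
cohort_fidelity(co, cfg)
#> <fidelity_report> cohort n = 1000
#>   ethnicity        chi2 =   5.08, df = 8, p = 0.7492
#>   age_group        chi2 =   3.48, df = 4, p = 0.4807
#>   disability_type  chi2 =   9.92, df = 9, p = 0.3570
#>   relationship     chi2 =   7.65, df = 5, p = 0.1767
#>   parental         z = -1.6320, p = 0.0513 (obs 0.568 vs exp 0.593)
```

The interview delivered all 47 question points of the packaged bank exactly
once, recorded one interviewer note per answered question, stayed well under
the 6,144-token context window, and ended with a clean `<STOP>`. The fidelity
report shows no significant deviation between the sampled cohort and the
configured population expectations (all p > 0.05), which is the intended
behaviour when testing a cohort against its own generating configuration.

A command-line wrapper covers the same pipeline:

```sh
Rscript inst/cli/synthintake.R generate-patients   --n 100 --seed 7 --out run1
Rscript inst/cli/synthintake.R generate-transcripts --seed 7 --out run1
Rscript inst/cli/synthintake.R evaluate             --seed 7 --out run1
```

which writes `patients.jsonl` (+ provenance sidecar), one JSON + TXT
transcript per patient with a status index CSV, and `evaluation.json` /
`evaluation.md` with the heatmap tables as CSV.

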