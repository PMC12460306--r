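Package: synthintake
Title: Synthetic Psychiatric Patients and Structured Intake Interview Transcripts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Generates demographically calibrated synthetic psychiatric patient
    profiles and simulated structured intake interviews between two
    language-model agents (an interview assistant and a patient), together with
    an evaluation suite. Profiles are sampled from a population-statistics
    configuration (categorical and age/sex-conditional distributions) and
    enriched with narrative text through a pluggable chat backend; a
    deterministic scripted mock backend makes the whole pipeline runnable and
    testable offline, and an HTTP adapter targets Ollama-compatible servers.
    Interviews follow a header-structured question bank delivered in chunks
    with context dumping, a strict RESPONSE/Note/<STOP> message protocol, and
    prompt-adherence failure classification. Evaluation covers Distinct-1
    lexical diversity, a Duplicate Ratio redundancy measure, chi-square
    goodness-of-fit cohort validation and a one-sided z-test for parental
    status.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    curl,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
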