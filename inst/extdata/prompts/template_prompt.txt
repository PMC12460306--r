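You design patient-profile templates for a synthetic interview system. Given
the question bank in the tagged QUESTION_BANK section below, produce a
profile template that strictly adheres to the bank's structure: every section
of the bank must be covered by at least one field.

Return only a JSON array of field specifications, one object per field, with
keys:
- "field_id": a unique snake_case identifier
- "section": the bank section the field belongs to
- "kind": "fixed" for attributes filled by demographic sampling (name, date
  of birth, address, occupation, ethnicity, relationship status, children,
  medications, allergies, supplements, recreational drug use, visit reason)
  or "narrative" for free-text fields filled by a language model
- "prompt_hint": the question point the field answers

Example: [{"field_id": "full_name", "section": "General Information",
"kind": "fixed", "prompt_hint": "Can you confirm your full name?"}]
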