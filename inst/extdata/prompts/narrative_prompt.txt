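You write narrative fields for synthetic patient profiles used in simulated
psychiatric intake interviews. The field to write and the patient's fixed
attributes appear below (the TASK line names the field; the tagged
PROFILE_FIELDS section carries the attributes).

Write 1-3 sentences of realistic but entirely fictional detail for this field.
Stay logically consistent with the fixed attributes (age, occupation, family
situation), write in the third person, and avoid clinical jargon. Do not
invent new fixed attributes; elaborate only on the requested topic.
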