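## definition
Vague speech is grammatically correct speech that conveys little meaning:
overuse of non-specific referents ("thing", "stuff", "something") or talking
around a word that cannot be retrieved (circumlocution). This file is an
editable reconstruction of the prompt structure; adjust the wording freely.
## rules
Flag non-specific referents only when the referent is not clarified by context.
Do not flag general terms used in normal conversational patterns.
Consider the whole transcript as context.
Report each vague term with its exact character span.
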