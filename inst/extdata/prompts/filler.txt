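## definition
Filler speech consists of non-lexical vocalizations (for example "um", "uh",
"er") and stray letter sounds used to buy speech-planning time, often in
place of a silent pause. This file is an editable reconstruction of the
prompt structure; adjust the wording freely.
## rules
Flag only non-lexical vocalizations, never content words.
Do not flag event tags such as [<event>] or bracketed annotations.
Do not flag repeated words; those belong to the repetition detector.
Report each occurrence separately with its exact character span.
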