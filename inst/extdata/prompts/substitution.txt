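## definition
A substitution error is the production of an unintended word in place of the
intended one, including phonemic, semantic, and neologistic paraphasias,
morphological errors, and intra-word dysfluencies. This file is an editable
reconstruction of the prompt structure; adjust the wording freely.
## rules
Flag words that are contextually inappropriate or not real words.
Consider the whole transcript as context before flagging a word.
Provide a brief justification for every flagged word.
Do not flag fillers, repetitions, or vague but grammatical wording.
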