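## definition
Repetitive speech is the involuntary, verbatim repeat of a whole word within
a short distance of its previous occurrence in the same utterance. This file
is an editable reconstruction of the prompt structure; adjust the wording
freely.
## rules
Flag only verbatim whole-word repeats; ignore revisions of word forms.
Ignore distant repetitions (more than a few words apart).
Report the span of the first occurrence as "span" and of the repeat as "span2".
Do not flag deliberate rhetorical repetition.
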