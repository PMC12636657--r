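# Default vague-speech keyword set: non-specific referents.
# One term per line; replace this file to override the defaults entirely.
thing
things
stuff
something
someone
somebody
somewhere
whatever
whatchamacallit
thingy
whatsit
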