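# curated alias map: raw token -> lexicon word
# aliases are a last-resort manual stage; ambiguous base forms must not
# be aliased (e.g. "after" is NOT mapped to "afterlife")
unafraid,fear
deathly,death
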