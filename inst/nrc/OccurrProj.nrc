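# Project sample id and the gene/impact attributes, preserving nesting.
OccurrProj := for o in Occurrences union
  { sid := o.sid,
    candidates := for c in o.candidates union
      { gene := c.gene, impact := c.impact } }
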