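# Annotate every candidate gene with its copy number in the same sample.
OccurCNV := for o in Occurrences union
  { sid := o.sid,
    candidates := for c in o.candidates union
      for n in CopyNumber union
        if (n.sid == o.sid && n.gene == c.gene) then
          { gene := c.gene, impact := c.impact, cnum := n.cnum } }
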