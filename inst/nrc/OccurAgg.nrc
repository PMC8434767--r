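# Per occurrence, sum impact x copy number over the unique candidate genes.
OccurAgg := for o in Occurrences union
  { sid := o.sid,
    scores := sumBy[gene; score](
      for c in o.candidates union
        for n in CopyNumber union
          if (n.sid == o.sid && n.gene == c.gene) then
            { gene := c.gene, score := c.impact * n.cnum } ) }
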