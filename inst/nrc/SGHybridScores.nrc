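# Sample-grouped hybrid scores: aggregate impact x copy number per gene,
# then group the per-gene scores by sample.
SGHybridScores := groupBy[sid -> scores](
  sumBy[sid, gene; score](
    for o in Occurrences union
      for c in o.candidates union
        for n in CopyNumber union
          if (n.sid == o.sid && n.gene == c.gene) then
            { sid := o.sid, gene := c.gene, score := c.impact * n.cnum } ) )
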