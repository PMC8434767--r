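# Stage 1 of the driver-gene pipeline: per sample (sid/aliquot), aggregate
# impact x consequence score x copy number over candidate genes.
HybridScores := for s in Samples union
  { sid := s.sid, aliquot := s.aliquot,
    scores := sumBy[gene; score](
      for o in Occurrences union
        if (o.sid == s.sid) then
          for c in o.candidates union
            for q in c.consequences union
              for i in SOImpact union
                if (i.conseq == q.conseq) then
                  for n in CopyNumber union
                    if (n.sid == s.sid && n.gene == c.gene) then
                      { gene := c.gene, score := c.impact * i.score * n.cnum } ) }
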