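# Group occurrences by sample, scoring consequence terms at the lowest level.
OccurGrouped := for s in Samples union
  { sid := s.sid,
    mutations := for o in Occurrences union
      if (o.sid == s.sid) then
        { contig := o.contig, start := o.start, end := o.end,
          reference := o.reference, alternate := o.alternate,
          mutationId := o.mutationId,
          candidates := for c in o.candidates union
            { gene := c.gene, impact := c.impact, sift := c.sift,
              poly := c.poly,
              consequences := for q in c.consequences union
                for i in SOImpact union
                  if (i.conseq == q.conseq) then
                    { conseq := q.conseq, score := i.score } } } }
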