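# Aggregate impact x consequence score x copy number per candidate gene,
# within each mutation, grouped by sample.
OccurCNVAgg := for s in Samples union
  { sid := s.sid,
    mutations := for o in Occurrences union
      if (o.sid == s.sid) then
        { contig := o.contig, start := o.start, end := o.end,
          reference := o.reference, alternate := o.alternate,
          mutationId := o.mutationId,
          candidates := sumBy[gene; score](
            for c in o.candidates union
              for q in c.consequences union
                for i in SOImpact union
                  if (i.conseq == q.conseq) then
                    for n in CopyNumber union
                      if (n.sid == s.sid && n.gene == c.gene) then
                        { gene := c.gene, score := c.impact * i.score * n.cnum } ) } }
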