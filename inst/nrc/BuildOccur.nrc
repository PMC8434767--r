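# Reconstruct the occurrences source by joining somatic mutations to their
# shared annotations on mutationId.
BuildOccur := for m in Mutations union
  { sid := m.sid, contig := m.contig, start := m.start, end := m.end,
    reference := m.reference, alternate := m.alternate,
    mutationId := m.mutationId,
    candidates := for a in Annotations union
      if (a.mutationId == m.mutationId) then
        for c in a.candidates union
          { gene := c.gene, impact := c.impact, sift := c.sift,
            poly := c.poly,
            consequences := for q in c.consequences union
              { conseq := q.conseq } } }
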