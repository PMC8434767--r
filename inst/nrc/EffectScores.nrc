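# Stage 3: effect score = accumulated edge-based network score of the
# gene's protein node plus the gene's own hybrid score.
EffectScores := for h in HybridScores union
  { sid := h.sid, aliquot := h.aliquot,
    scores := sumBy[gene; score](
      for c in h.scores union
        { gene := c.gene, score := c.score }
      ++
      for c in h.scores union
        for g in GeneMap union
          if (g.gene == c.gene) then
            for w in HybridNetworks union
              if (w.sid == h.sid && w.aliquot == h.aliquot) then
                for d in w.nodes union
                  if (d.nodeProtein == g.protein) then
                    { gene := c.gene, score := d.score } ) }
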