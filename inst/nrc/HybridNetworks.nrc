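# Stage 2: per sample, weight each network edge by the hybrid score of the
# gene mapped to its edge protein, and sum per node protein.
HybridNetworks := for h in HybridScores union
  { sid := h.sid, aliquot := h.aliquot,
    nodes := sumBy[nodeProtein; score](
      for c in h.scores union
        for g in GeneMap union
          if (g.gene == c.gene) then
            for e in Network union
              if (e.edgeProtein == g.protein) then
                { nodeProtein := e.nodeProtein, score := c.score * e.distance } ) }
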