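# Stage 4: connection score = effect score x expression (FPKM) per gene.
ConnectScores := for s in EffectScores union
  { sid := s.sid, aliquot := s.aliquot,
    scores := sumBy[gene; score](
      for c in s.scores union
        for x in GeneExpression union
          if (x.aliquot == s.aliquot && x.gene == c.gene) then
            { gene := c.gene, score := c.score * x.fpkm } ) }
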