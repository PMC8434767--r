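# Stage 5: gene connectivity = connection scores summed across all samples.
Connectivity := sumBy[gene; score](
  for s in ConnectScores union
    for c in s.scores union
      { gene := c.gene, score := c.score } )
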