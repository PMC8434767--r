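# Label each sample's pathway burden features with its tumor site.
BurdenFeatures := for s in Samples union
  { sid := s.sid, tumorsite := s.tumorsite,
    burdens := for p in PathwayBurden union
      for b in p.burdens union
        if (b.sid == s.sid) then
          { pathway := p.pathway, burden := b.burden } }
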