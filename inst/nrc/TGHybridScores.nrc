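# Tumor-site-grouped hybrid scores, written in the explicit dedup form:
# a deduplicated bag of tumor sites drives the top-level grouping.
TumorSites := dedup(for s in Samples union { tumorsite := s.tumorsite })
TGHybridScores := for t in TumorSites union
  { tumorsite := t.tumorsite,
    samples := for s in Samples union
      if (s.tumorsite == t.tumorsite) then
        { sid := s.sid,
          scores := sumBy[gene; score](
            for o in Occurrences union
              if (o.sid == s.sid) then
                for c in o.candidates union
                  for n in CopyNumber union
                    if (n.sid == o.sid && n.gene == c.gene) then
                      { gene := c.gene, score := c.impact * n.cnum } ) } }
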