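# Pathway mutational burden: per pathway, sum candidate impact scores of the
# member genes for each sample.
PathwayBurden := for p in Pathways union
  { pathway := p.pathway,
    burdens := sumBy[sid; burden](
      for o in Occurrences union
        for c in o.candidates union
          for g in p.genes union
            if (c.gene == g.gene) then
              { sid := o.sid, burden := c.impact } ) }
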