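# Gene mutational burden: per gene, sum the genotype calls of every sample
# over the variants lying within the gene's mapped position.
GeneBurden := for g in GeneMap union
  { gene := g.gene,
    burdens := sumBy[sid; burden](
      for v in Variants union
        if (v.contig == g.contig && g.start <= v.start && v.start <= g.end) then
          for t in v.genotypes union
            { sid := t.sid, burden := t.call } ) }
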