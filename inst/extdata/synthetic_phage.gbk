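LOCUS       SYNPHAGE1                240 bp    DNA     linear   PHG 01-JAN-2026
DEFINITION  Synthetic miniature phage genome for parser validation.
ACCESSION   SYNPHAGE1
FEATURES             Location/Qualifiers
     source          1..240
                     /organism="synthetic construct"
     CDS             10..69
                     /product="endolysin"
                     /function="lysis"
     CDS             complement(80..139)
                     /product="holin"
                     /function="lysis"
     tRNA            150..190
                     /product="tRNA-Gly"
     misc_feature    200..220
                     /product="spacer"
ORIGIN
        1 atgcatgcat gcatgcatgc atgcatgcat gcatgcatgc atgcatgcat gcatgcatgc
       61 ggggccccgg ggccccgggg ccccggggcc ccggggcccc ggggccccgg ggccccgggg
      121 atatatatat atatatatat atatatatat atatatatat atatatatat atatatatat
      181 cgcgcgcgcg cgcgcgcgcg cgcgcgcgcg cgcgcgcgcg cgcgcgcgcg cgcgcgcgcg
//
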