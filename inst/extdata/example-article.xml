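<article>
  <front>
    <article-meta>
      <article-id>nx1</article-id>
      <title-group>
        <article-title>Membrane transport in yeast</article-title>
      </title-group>
      <abstract><p>Transport was measured in mutant strains.</p></abstract>
    </article-meta>
  </front>
  <body>
    <sec>
      <title>Results</title>
      <p>Uptake rose in mutants. Figure 2 shows uptake kinetics. Figure 1 shows strain construction.</p>
      <fig id="f2">
        <label>Figure 2</label>
        <caption><p>Uptake kinetics in <italic>mutant</italic> strains.</p></caption>
      </fig>
      <fig id="f1">
        <label>Figure 1</label>
        <caption><p>Strain construction.</p></caption>
      </fig>
    </sec>
  </body>
</article>
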