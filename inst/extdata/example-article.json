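{
  "article_id": "ex1",
  "title": "Kinase signaling controls cell growth",
  "abstract": "We show that kinase signaling controls growth. Figure 2 summarizes the main pathway.",
  "sections": [
    {
      "heading": "Introduction",
      "paragraphs": [
        "Cell growth is regulated by kinase cascades. Prior work focused on receptor binding."
      ]
    },
    {
      "heading": "Materials and Methods",
      "paragraphs": [
        "Cells were cultured and treated as described. Lysates were analyzed by blotting."
      ]
    },
    {
      "heading": "Results",
      "paragraphs": [
        "Treatment increased kinase activity. As shown in Figure 1, activity doubled. Controls were unchanged. The effect was dose dependent. A further assay confirmed this.",
        "The pathway map is central to our model. Figure 2 shows the kinase pathway. Figures 2 and 3 share the reporter assay. Binding was specific."
      ]
    },
    {
      "heading": "Discussion",
      "paragraphs": [
        "Our data support a central role for the pathway in Fig. 2. Future work will test in vivo relevance."
      ]
    }
  ],
  "figures": [
    {"label": "1", "caption": "Kinase activity after treatment. (A) time course (B) dose response."},
    {"label": "2", "caption": "The kinase signaling pathway controlling growth."},
    {"label": "3", "caption": "Reporter assay specificity."}
  ]
}
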