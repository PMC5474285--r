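BDCA4+ dendritic cells
bone marrow
CD14+ monocytes
CD19+ B cells
CD33+ myeloid
CD34+ hematopoietic stem cells
CD4+ T cells
CD56+ NK cells
CD8+ T cells
colon
colorectal adenocarcinoma
liver
lymph nodes
lymphoblasts
small intestine
smooth muscle
thymus
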