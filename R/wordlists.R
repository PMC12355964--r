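# Packaged name pools for the synthetic corpus. Enzyme and organism names
# are all at least ten characters, so a single-character typo stays above
# the 90% similarity threshold used for key matching.

synthetic_enzymes <- c(
  "alcohol dehydrogenase", "beta-galactosidase", "carbonic anhydrase",
  "alkaline phosphatase", "glucose oxidase", "lysozyme variant c",
  "triosephosphate isomerase", "dihydrofolate reductase",
  "aspartate aminotransferase", "pyruvate kinase", "hexokinase isoform 2",
  "chymotrypsin precursor", "acetylcholinesterase", "glutathione transferase",
  "ornithine decarboxylase", "phosphoglycerate mutase",
  "fructose bisphosphate aldolase", "isocitrate dehydrogenase",
  "glucose 6-phosphate dehydrogenase", "adenylate kinase"
)

synthetic_organisms <- c(
  "Escherichia coli", "Saccharomyces cerevisiae", "Homo sapiens",
  "Bacillus subtilis", "Thermus thermophilus", "Pseudomonas putida",
  "Arabidopsis thaliana", "Rattus norvegicus", "Drosophila melanogaster",
  "Mycobacterium tuberculosis", "Pyrococcus furiosus",
  "Lactococcus lactis", "Aspergillus niger", "Thermotoga maritima"
)

synthetic_substrates <- c(
  "glucose", "lactose", "sucrose", "maltose", "pyruvate", "oxaloacetate",
  "benzaldehyde", "acetaldehyde", "p-nitrophenyl phosphate",
  "p-nitrophenyl acetate", "dihydrofolate", "fructose 6-phosphate",
  "glyceraldehyde 3-phosphate", "acetylcholine", "glutathione",
  "ornithine", "citrate", "isocitrate", "adenosine triphosphate",
  "phosphoenolpyruvate", "galactose", "xylose", "cellobiose", "trehalose"
)

synthetic_filler_sentences <- c(
  "Kinetic assays were performed in triplicate at the stated conditions.",
  "Initial rates were obtained from the linear phase of product formation.",
  "Protein concentration was determined by absorbance at 280 nm.",
  "All reagents were of analytical grade and used without purification.",
  "Steady-state parameters were obtained by nonlinear regression.",
  "Measurements were corrected for the uncatalyzed background reaction."
)
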