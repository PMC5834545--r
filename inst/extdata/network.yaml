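# Plasma-membrane phosphoinositide interconversion network (1 um^2 patch).
#
# Species ids encode the phosphorylated positions of the inositol ring as a
# digit string ("0" = unphosphorylated PI, "345" = PI(3,4,5)P3), so that every
# interconversion flux label v<i>-><j> is mechanical.
#
# Interconversions: 9 phosphorylations (kinases) + 12 hydrolyses
# (phosphatases) = 21 reactions, each 1:1 in stoichiometry. Transport: three
# influxes (PI from the ER, PI(4)P from the Golgi, PI(3)P from endosomes) and
# one first-order efflux per species sharing a common rate constant.
#
# Enzyme assignments follow standard phosphoinositide biochemistry:
#   PI4K          PI -> PI(4)P
#   PIP5KI        PI(4)P -> PI(4,5)P2 (type I PIP kinase, 5-position)
#   PIP5KII       PI(5)P -> PI(4,5)P2 (type II PIP kinase, 4-position)
#   PI3KI         PI(4,5)P2 -> PI(3,4,5)P3 (class I PI3K)
#   PI3KII        PI -> PI(3)P and PI(4)P -> PI(3,4)P2 (class II/III PI3K)
#   PIKfyve       PI -> PI(5)P and PI(3)P -> PI(3,5)P2
#   PTEN          PI(3,4,5)P3 -> PI(4,5)P2 and (weakly) PI(3,4)P2 -> PI(4)P
#   SHIP          PI(3,4,5)P3 -> PI(3,4)P2 (5-phosphatase)
#   SIOSS         PI(4,5)P2 -> PI(4)P (grouped 5-phosphatases: SYNJ1/2,
#                 INPP5B/J/E, OCRL1, SAC2, SKIP)
#   SYNJ_TMEM55   PI(4,5)P2 -> PI(5)P (4-phosphatases)
#   SYNJ          PI(4,5)P2 -> PI (synaptojanin tandem 5-phosphatase + SAC1
#                 domains acting processively)
#   SAC1          PI(4)P -> PI
#   MTMR          PI(3)P -> PI and PI(3,5)P2 -> PI(5)P (myotubularins)
#   INPP4         PI(3,4)P2 -> PI(3)P (4-phosphatases INPP4A/B)
#   FIG4          PI(3,5)P2 -> PI(3)P (SAC3/FIG4 5-phosphatase)
#   PI5P_PASE     PI(5)P -> PI; the responsible phosphatase is not firmly
#                 identified in the literature (AMBIGUOUS assignment, kept as
#                 an anonymous group rather than guessing a gene name)
#   PI4K_PIP5KI_DVL  ternary complex channelling PI directly to PI(4,5)P2;
#                 knocking out either kinase component removes the complex,
#                 knocking out only the complex leaves v0->4 and v4->45 intact

time_unit: minutes

species:
  - {id: "0",   name: "PI",          basal_abundance: 500000}
  - {id: "3",   name: "PI(3)P",      basal_abundance: 500}
  - {id: "4",   name: "PI(4)P",      basal_abundance: 10000}
  - {id: "5",   name: "PI(5)P",      basal_abundance: 300}
  - {id: "34",  name: "PI(3,4)P2",   basal_abundance: 150}
  - {id: "35",  name: "PI(3,5)P2",   basal_abundance: 50}
  - {id: "45",  name: "PI(4,5)P2",   basal_abundance: 10000}
  - {id: "345", name: "PI(3,4,5)P3", basal_abundance: 20}

fluxes:
  # phosphorylations (kinases)
  - {id: "v0->3",    kind: phosphorylation, substrate: "0",   product: "3",   enzyme: PI3KII}
  - {id: "v0->4",    kind: phosphorylation, substrate: "0",   product: "4",   enzyme: PI4K}
  - {id: "v0->5",    kind: phosphorylation, substrate: "0",   product: "5",   enzyme: PIKfyve}
  - {id: "v0->45",   kind: phosphorylation, substrate: "0",   product: "45",  enzyme: PI4K_PIP5KI_DVL}
  - {id: "v4->45",   kind: phosphorylation, substrate: "4",   product: "45",  enzyme: PIP5KI}
  - {id: "v4->34",   kind: phosphorylation, substrate: "4",   product: "34",  enzyme: PI3KII}
  - {id: "v5->45",   kind: phosphorylation, substrate: "5",   product: "45",  enzyme: PIP5KII}
  - {id: "v3->35",   kind: phosphorylation, substrate: "3",   product: "35",  enzyme: PIKfyve}
  - {id: "v45->345", kind: phosphorylation, substrate: "45",  product: "345", enzyme: PI3KI}
  # hydrolyses (phosphatases)
  - {id: "v3->0",    kind: hydrolysis, substrate: "3",   product: "0",  enzyme: MTMR}
  - {id: "v4->0",    kind: hydrolysis, substrate: "4",   product: "0",  enzyme: SAC1}
  - {id: "v5->0",    kind: hydrolysis, substrate: "5",   product: "0",  enzyme: PI5P_PASE}
  - {id: "v45->0",   kind: hydrolysis, substrate: "45",  product: "0",  enzyme: SYNJ}
  - {id: "v45->4",   kind: hydrolysis, substrate: "45",  product: "4",  enzyme: SIOSS}
  - {id: "v45->5",   kind: hydrolysis, substrate: "45",  product: "5",  enzyme: SYNJ_TMEM55}
  - {id: "v345->45", kind: hydrolysis, substrate: "345", product: "45", enzyme: PTEN}
  - {id: "v345->34", kind: hydrolysis, substrate: "345", product: "34", enzyme: SHIP}
  - {id: "v34->4",   kind: hydrolysis, substrate: "34",  product: "4",  enzyme: PTEN}
  - {id: "v34->3",   kind: hydrolysis, substrate: "34",  product: "3",  enzyme: INPP4}
  - {id: "v35->5",   kind: hydrolysis, substrate: "35",  product: "5",  enzyme: MTMR}
  - {id: "v35->3",   kind: hydrolysis, substrate: "35",  product: "3",  enzyme: FIG4}
  # transport into the patch
  - {id: "v->0", kind: influx, product: "0"}
  - {id: "v->4", kind: influx, product: "4"}
  - {id: "v->3", kind: influx, product: "3"}
  # transport out of the patch (first order, shared rate constant)
  - {id: "v0->",   kind: efflux, substrate: "0"}
  - {id: "v3->",   kind: efflux, substrate: "3"}
  - {id: "v4->",   kind: efflux, substrate: "4"}
  - {id: "v5->",   kind: efflux, substrate: "5"}
  - {id: "v34->",  kind: efflux, substrate: "34"}
  - {id: "v35->",  kind: efflux, substrate: "35"}
  - {id: "v45->",  kind: efflux, substrate: "45"}
  - {id: "v345->", kind: efflux, substrate: "345"}

# Ternary complexes: scaling (or knocking out) any component enzyme propagates
# to the complex; perturbing only the complex leaves components untouched.
complexes:
  PI4K_PIP5KI_DVL: [PI4K, PIP5KI]
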