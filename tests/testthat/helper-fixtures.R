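# Toy repositioning universe. Query disease XQ; class {XQ, XC}. P0 anchors
# XQ's neighborhood; P1..P3, P5 are class target proteins via XC. Drugs:
#   D1 passes everything; D2 already treats class disease XC; D3 unapproved;
#   D4 shares a direct neighbor with XQ (shared count 1); D5 scores zero;
#   D6 is already linked to XQ itself.
reposition_toy <- function() {
  edges <- tibble::tibble(
    source_id = c("P0", "D1", "P1", "P1", "D2", "P2", "P2", "D2",
      "D3", "P3", "P3", "D4", "D5", "P5", "D6"),
    source_kind = c("protein", "drug", "protein", "protein", "drug", "protein",
      "protein", "drug", "drug", "protein", "protein", "drug", "drug",
      "protein", "drug"),
    target_id = c("XQ", "P1", "XC", "P0", "P2", "XC", "P0", "XC",
      "P3", "XC", "P0", "P0", "P5", "XC", "XQ"),
    target_kind = c("disease", "protein", "disease", "protein", "protein",
      "disease", "protein", "disease", "protein", "disease", "protein",
      "protein", "protein", "disease", "disease")
  )
  pharm_graph(edges)
}

toy_bank <- function() manual_calibration_bank(c("1" = 0.05))
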