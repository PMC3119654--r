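# Electrophysiology solution registry (concentrations in mM).
# E* = bath (external), P* = pipette (internal).  Chloride is the sum over
# the chloride salts of each recipe; NMDG is assumed titrated to its
# chloride.  Free H+ is always derived from pH, never listed here.
E1:            # artificial seawater bath (coccolithophore recordings)
  ions: {Na: 452, K: 8, Cl: 538, Ca: 10, Mg: 46}
  pH: 8.0
  buffer: "HEPES 20"
E3:            # HEK293 bath, Zn2+ experiments
  ions: {Na: 160, K: 2, Cl: 166, Ca: 1, Mg: 1}
  pH: 7.8
  buffer: "HEPES 100"
E4:            # HEK293 NMDG bath
  ions: {Na: 0, K: 0, Cl: 83, Ca: 1, Mg: 3}
  pH: 7.8
  buffer: "HEPES 100"
E5:            # HEK293 NMDG bath at low pH (MES-buffered)
  ions: {Na: 0, K: 0, Cl: 83, Ca: 1, Mg: 3}
  pH: 6.5
  buffer: "MES 100"
P1a:           # K-glutamate 200 pipette, strongly buffered
  ions: {Na: 0, K: 200, Cl: 10, Ca: 0, Mg: 5}
  pH: 7.5
  buffer: "HEPES 100"
P1b:           # K-glutamate 200 pipette, weakly buffered (BCECF loading)
  ions: {Na: 0, K: 200, Cl: 10, Ca: 0, Mg: 5}
  pH: 7.2
  buffer: "PIPES 1"
P2:            # TEA-Cl pipette (K+-free)
  ions: {Na: 0, K: 0, Cl: 210, Ca: 0, Mg: 5}
  pH: 7.5
  buffer: "HEPES 5"
P3:            # HEK293 NaCl/KCl pipette
  ions: {Na: 30, K: 100, Cl: 136, Ca: 0, Mg: 3}
  pH: 7.0
  buffer: "HEPES 100"
P4:            # HEK293 NMDG pipette
  ions: {Na: 0, K: 0, Cl: 71, Ca: 0, Mg: 3}
  pH: 7.0
  buffer: "HEPES 150"
P_KCl80:       # tail-protocol pipette, low Cl-
  ions: {Na: 0, K: 80, Cl: 90, Ca: 0, Mg: 5}
  pH: 7.5
  buffer: "HEPES 5"
P_KCl400:      # tail-protocol pipette, high K+/Cl-
  ions: {Na: 0, K: 400, Cl: 410, Ca: 0, Mg: 5}
  pH: 7.5
  buffer: "HEPES 5"
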