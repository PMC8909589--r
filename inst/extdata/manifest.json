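{
  "electron_yields.csv": {
    "description": "DNA damage yields for monoenergetic electrons (100 eV - 4.5 keV): clustered-damage simulation versus published track-structure simulations. Percentages are shares of all damage clusters; totals are per Gy per Gbp with 'value ± sem' cells where reported.",
    "conditions": "21% O2",
    "columns": "class percentages BD/SSB/SSB+/2SSB/DSB/DSB+/DSB++; total_ssb = SSB+SSB(+)+2SSB; total_dsb = DSB+DSB(+)+DSB(++)"
  },
  "photon_yields.csv": {
    "description": "DNA damage yields for Grenz-ray qualities (15 kV, 10 kV monoenergetic, 10 kVp tube spectrum, 4.55 kV titanium K-shell) and Co-60 reference, at 21%, 2% and 0.1% O2. One track-structure comparison row (4.55 kV, percentages only).",
    "conditions": "o2_percent column: 21, 2, 0.1"
  },
  "qualities.csv": {
    "description": "Radiation-quality metadata: mean photon energy (kV), LET (keV/um), measured DSB yields and RBE where available, simulated DSB yields and one-decimal RBE for DSB induction relative to Co-60.",
    "note": "n = 10000 samples behind every simulated 'value ± sem' cell"
  }
}
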