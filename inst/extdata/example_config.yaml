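# Minimal simulation + analysis configuration: two pure populations, an F1
# hybrid, a somatic clone, and one introgressed founder. Scale is kept small
# so the example runs in seconds; see ?population_model for the defaults a
# real analysis would use.
seed: 2021
model:
  pops: [RK, MA, MS, PU]
  F: {RK: 0.80, MA: 0.54, MS: 0.44, PU: 0.84}
  n_chrom: 2
  chrom_bp: 10000000
  sites_per_chrom: 20000
  crossover_rate: 1.3
pedigree:
  - {id: RK1, role: founder, pop: RK}
  - {id: RK2, role: founder, pop: RK}
  - {id: RK3, role: founder, pop: RK}
  - {id: RK4, role: founder, pop: RK}
  - {id: MA1, role: founder, pop: MA}
  - {id: MA2, role: founder, pop: MA}
  - {id: MA3, role: founder, pop: MA}
  - {id: MA4, role: founder, pop: MA}
  - {id: MS1, role: founder, pop: MS}
  - {id: MS2, role: founder, pop: MS}
  - {id: PU1, role: founder, pop: PU}
  - {id: PU2, role: founder, pop: PU}
  - {id: PU3, role: founder, pop: PU}
  - {id: HYB, role: f1, parentA: RK1, parentB: MA1, depth: 40}
  - {id: HYBc, role: clone, source: HYB, somatic_rate: 0.00001, depth: 25}
  - id: INTRO
    role: introgressed
    recipient: MA
    donor: PU
    segments:
      - {chrom: chr2, start: 4000000, end: 6400000}
windows:
  bp_span: 200000
  het_sites: 2000
  aims: 500
  min_aims_per_pop: 5
thresholds:
  ibsr: 0.95
  d: 0.05
  hap_mismatch: 0.0002
  clone_d: 0.02
  epsilon: 0.01
  margin: 2
  min_informative: 50
exemplars:
  RK: [RK1, RK2, RK3]
  MA: [MA1, MA2, MA3]
  MS: [MS1, MS2]
  PU: [PU1, PU2, PU3]
phase:
  hybrids: [HYB]
  panelA: [RK2, RK3, RK4]
  panelB: [MA2, MA3, MA4]
  candidates: [RK1, MA1, MS1]
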