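# Study-like simulated pull-down design: four GFP-bait strains plus WT,
# triplicates, PSI:PSII copy ratio 4.5, log-normal measurement noise, and
# a sticky background proteome so that 180 proteins are detected in total.
seed: 20210714
alpha: 0.05
label_fold: 20
simulate:
  replicates: 3
  copy_number: {PSI: 4.5, PSII: 1.0, CYTB6F: 0.7, ATPASE: 0.5, NDH1: 0.4}
  supercomplex_count:
    - {a: PSI, b: PSII, n: 0.099}     # 9.9% of PSII engaged with PSI
    - {a: PSI, b: CYTB6F, n: 0.0287}  # 4.1% of Cyt b6f engaged with PSI
    - {a: PSII, b: CYTB6F, n: 0.014}  # 2.0% of Cyt b6f engaged with PSII
    - {a: PSI, b: ATPASE, n: 0.005}
    - {a: PSII, b: ATPASE, n: 0.005}
    - {a: CYTB6F, b: ATPASE, n: 0.005}
    - {a: PSI, b: NDH1, n: 0.02}
  stoichiometry: 1
  noise_sd: 0.2
  background: 0.002          # nonspecific rate of every mapped subunit
  extra_proteins:            # unmapped sticky proteins seen in WT too
    count: 135
    rate: 0.05
    prefix: Nsb
  interface_boost:           # interface-proximity co-capture enrichment
    - {protein: PsaK, bait: PSII, multiplier: 3}
    - {protein: PsaK, bait: CYTB6F, multiplier: 3}
    - {protein: PsaK, bait: ATPASE, multiplier: 3}
    - {protein: PetM, bait: PSI, multiplier: 3}
    - {protein: PetM, bait: PSII, multiplier: 3}
    - {protein: AtpF2_bprime, bait: PSI, multiplier: 3}
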