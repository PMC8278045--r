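{
  "gfp_id": "GFP",
  "membership": {
    "PsaA": "PSI",
    "PsaB": "PSI",
    "PsaC": "PSI",
    "PsaD": "PSI",
    "PsaE": "PSI",
    "PsaF": "PSI",
    "PsaJ": "PSI",
    "PsaK": "PSI",
    "PsaL": "PSI",
    "PsbA": "PSII",
    "PsbB": "PSII",
    "PsbC": "PSII",
    "PsbD": "PSII",
    "PsbE": "PSII",
    "PsbF": "PSII",
    "PsbO": "PSII",
    "PsbU": "PSII",
    "PsbV": "PSII",
    "PsbN": "PSII",
    "PsbY": "PSII",
    "PetA": "CYTB6F",
    "PetB": "CYTB6F",
    "PetC": "CYTB6F",
    "PetD": "CYTB6F",
    "PetG": "CYTB6F",
    "PetL": "CYTB6F",
    "PetM": "CYTB6F",
    "PetN": "CYTB6F",
    "AtpA": "ATPASE",
    "AtpB": "ATPASE",
    "AtpC": "ATPASE",
    "AtpD": "ATPASE",
    "AtpE": "ATPASE",
    "AtpF": "ATPASE",
    "AtpF2_bprime": "ATPASE",
    "AtpG": "ATPASE",
    "AtpH": "ATPASE",
    "AtpI": "ATPASE",
    "NdhA": "NDH1",
    "NdhK": "NDH1",
    "NdhL": "NDH1",
    "NdhM": "NDH1",
    "NdhN": "NDH1",
    "NdhO": "NDH1",
    "NdhS": "NDH1"
  }
}
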