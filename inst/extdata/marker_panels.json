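{
  "panels": {
    "R1-6": ["ninaE"],
    "R7": ["Rh3", "Rh4", "pros"],
    "R8": ["Rh5", "Rh6", "sens"],
    "cone": ["ct", "Crys"],
    "pigment1": ["wrapper", "Pdh"],
    "pigment23": ["santa-maria", "w", "Pdh"],
    "noneye": ["fne", "moody", "repo"]
  },
  "forbidden": {
    "R1-6": ["Rh3", "Rh4", "Rh5", "Rh6"],
    "R7": ["Rh5", "Rh6", "ninaE"],
    "R8": ["Rh3", "Rh4", "ninaE"],
    "cone": ["ninaE", "Rh3", "Rh4", "Rh5", "Rh6"],
    "pigment1": ["ninaE", "Rh3", "Rh4", "Rh5", "Rh6"],
    "pigment23": ["ninaE", "Rh3", "Rh4", "Rh5", "Rh6"],
    "noneye": ["ninaE", "Rh3", "Rh4", "Rh5", "Rh6"]
  }
}
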