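{
  "version": "1.0",
  "activity": [
    "Diurnal",
    "Diurnal cathemeral",
    "Nocturnal cathemeral",
    "Crepuscular",
    "Near obligate nocturnal",
    "Obligate nocturnal"
  ],
  "habitat": [
    "Open",
    "Semi-open",
    "Closed"
  ],
  "diet": [
    "Invertivore",
    "Vertivore",
    "Aquatic invertivore",
    "Aquatic vertivore",
    "Aquatic herbivore",
    "Frugivore",
    "Granivore",
    "Nectarivore",
    "Herbivore",
    "Omnivore"
  ],
  "foraging_method": [
    "Skimming",
    "Dabbling",
    "Dipping",
    "Diving",
    "Gleaning",
    "Hawking",
    "Sallying",
    "Lunging",
    "Scratching",
    "Plunge diving",
    "Probing",
    "Scanning"
  ],
  "foraging_height": [
    "Low",
    "Various",
    "High"
  ]
}
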