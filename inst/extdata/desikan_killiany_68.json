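{
  "name": "desikan_killiany_68",
  "regions": [
    {
      "label": "bankssts",
      "hemisphere": "left"
    },
    {
      "label": "caudalanteriorcingulate",
      "hemisphere": "left"
    },
    {
      "label": "caudalmiddlefrontal",
      "hemisphere": "left"
    },
    {
      "label": "cuneus",
      "hemisphere": "left"
    },
    {
      "label": "entorhinal",
      "hemisphere": "left"
    },
    {
      "label": "fusiform",
      "hemisphere": "left"
    },
    {
      "label": "inferiorparietal",
      "hemisphere": "left"
    },
    {
      "label": "inferiortemporal",
      "hemisphere": "left"
    },
    {
      "label": "isthmuscingulate",
      "hemisphere": "left"
    },
    {
      "label": "lateraloccipital",
      "hemisphere": "left"
    },
    {
      "label": "lateralorbitofrontal",
      "hemisphere": "left"
    },
    {
      "label": "lingual",
      "hemisphere": "left"
    },
    {
      "label": "medialorbitofrontal",
      "hemisphere": "left"
    },
    {
      "label": "middletemporal",
      "hemisphere": "left"
    },
    {
      "label": "parahippocampal",
      "hemisphere": "left"
    },
    {
      "label": "paracentral",
      "hemisphere": "left"
    },
    {
      "label": "parsopercularis",
      "hemisphere": "left"
    },
    {
      "label": "parsorbitalis",
      "hemisphere": "left"
    },
    {
      "label": "parstriangularis",
      "hemisphere": "left"
    },
    {
      "label": "pericalcarine",
      "hemisphere": "left"
    },
    {
      "label": "postcentral",
      "hemisphere": "left"
    },
    {
      "label": "posteriorcingulate",
      "hemisphere": "left"
    },
    {
      "label": "precentral",
      "hemisphere": "left"
    },
    {
      "label": "precuneus",
      "hemisphere": "left"
    },
    {
      "label": "rostralanteriorcingulate",
      "hemisphere": "left"
    },
    {
      "label": "rostralmiddlefrontal",
      "hemisphere": "left"
    },
    {
      "label": "superiorfrontal",
      "hemisphere": "left"
    },
    {
      "label": "superiorparietal",
      "hemisphere": "left"
    },
    {
      "label": "superiortemporal",
      "hemisphere": "left"
    },
    {
      "label": "supramarginal",
      "hemisphere": "left"
    },
    {
      "label": "frontalpole",
      "hemisphere": "left"
    },
    {
      "label": "temporalpole",
      "hemisphere": "left"
    },
    {
      "label": "transversetemporal",
      "hemisphere": "left"
    },
    {
      "label": "insula",
      "hemisphere": "left"
    },
    {
      "label": "bankssts",
      "hemisphere": "right"
    },
    {
      "label": "caudalanteriorcingulate",
      "hemisphere": "right"
    },
    {
      "label": "caudalmiddlefrontal",
      "hemisphere": "right"
    },
    {
      "label": "cuneus",
      "hemisphere": "right"
    },
    {
      "label": "entorhinal",
      "hemisphere": "right"
    },
    {
      "label": "fusiform",
      "hemisphere": "right"
    },
    {
      "label": "inferiorparietal",
      "hemisphere": "right"
    },
    {
      "label": "inferiortemporal",
      "hemisphere": "right"
    },
    {
      "label": "isthmuscingulate",
      "hemisphere": "right"
    },
    {
      "label": "lateraloccipital",
      "hemisphere": "right"
    },
    {
      "label": "lateralorbitofrontal",
      "hemisphere": "right"
    },
    {
      "label": "lingual",
      "hemisphere": "right"
    },
    {
      "label": "medialorbitofrontal",
      "hemisphere": "right"
    },
    {
      "label": "middletemporal",
      "hemisphere": "right"
    },
    {
      "label": "parahippocampal",
      "hemisphere": "right"
    },
    {
      "label": "paracentral",
      "hemisphere": "right"
    },
    {
      "label": "parsopercularis",
      "hemisphere": "right"
    },
    {
      "label": "parsorbitalis",
      "hemisphere": "right"
    },
    {
      "label": "parstriangularis",
      "hemisphere": "right"
    },
    {
      "label": "pericalcarine",
      "hemisphere": "right"
    },
    {
      "label": "postcentral",
      "hemisphere": "right"
    },
    {
      "label": "posteriorcingulate",
      "hemisphere": "right"
    },
    {
      "label": "precentral",
      "hemisphere": "right"
    },
    {
      "label": "precuneus",
      "hemisphere": "right"
    },
    {
      "label": "rostralanteriorcingulate",
      "hemisphere": "right"
    },
    {
      "label": "rostralmiddlefrontal",
      "hemisphere": "right"
    },
    {
      "label": "superiorfrontal",
      "hemisphere": "right"
    },
    {
      "label": "superiorparietal",
      "hemisphere": "right"
    },
    {
      "label": "superiortemporal",
      "hemisphere": "right"
    },
    {
      "label": "supramarginal",
      "hemisphere": "right"
    },
    {
      "label": "frontalpole",
      "hemisphere": "right"
    },
    {
      "label": "temporalpole",
      "hemisphere": "right"
    },
    {
      "label": "transversetemporal",
      "hemisphere": "right"
    },
    {
      "label": "insula",
      "hemisphere": "right"
    }
  ]
}
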