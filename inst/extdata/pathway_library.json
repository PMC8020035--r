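{
  "description": "Small synthetic pathway graph library for urinary metabolites. Undirected edges encode reaction adjacency; node identifiers follow KEGG-style compound codes. Synthetic fixture: topologies are simplified toy versions of the named pathways, not a database export.",
  "background": [
    "C00262", "C00385", "C00294", "C00212", "C00366", "C00130", "C00020", "C00242",
    "C07481", "C07480", "C13747", "C16358",
    "C00082", "C00355", "C03758", "C05580", "C11527", "C01179", "C05582",
    "C00183", "C00123", "C00407", "C00141", "C00233",
    "C00037", "C00065", "C00188", "C00719", "C00213",
    "C00158", "C00042", "C00122", "C00149", "C00036", "C00026",
    "C00022", "C00186", "C00033", "C00024",
    "C00791", "C00300", "C02305", "C02565",
    "C00135", "C00386", "C01152", "C00785",
    "C02918", "C00153", "C00003",
    "C00245", "C00519", "C00097",
    "C01089", "C00246", "C00164",
    "C00031", "C00058", "C01104", "C00543", "C01586", "C21593",
    "C01551", "C01004", "C00041"
  ],
  "pathways": [
    {
      "id": "pw_purine",
      "name": "Purine metabolism",
      "nodes": ["C00020", "C00130", "C00294", "C00262", "C00385", "C00366", "C00212", "C00242"],
      "edges": [
        ["C00020", "C00130"], ["C00130", "C00294"], ["C00294", "C00262"],
        ["C00262", "C00385"], ["C00385", "C00366"], ["C00020", "C00212"],
        ["C00212", "C00294"], ["C00242", "C00385"]
      ]
    },
    {
      "id": "pw_caffeine",
      "name": "Caffeine metabolism",
      "nodes": ["C07481", "C13747", "C07480", "C16358", "C00385"],
      "edges": [
        ["C07481", "C13747"], ["C07481", "C07480"],
        ["C13747", "C16358"], ["C16358", "C00385"]
      ]
    },
    {
      "id": "pw_tyrosine",
      "name": "Tyrosine metabolism",
      "nodes": ["C00082", "C00355", "C03758", "C05580", "C11527", "C01179", "C05582"],
      "edges": [
        ["C00082", "C00355"], ["C00355", "C03758"], ["C03758", "C05580"],
        ["C05580", "C11527"], ["C00082", "C01179"], ["C03758", "C05582"]
      ]
    },
    {
      "id": "pw_bcaa",
      "name": "Valine, leucine and isoleucine degradation",
      "nodes": ["C00183", "C00123", "C00407", "C00141", "C00233"],
      "edges": [
        ["C00183", "C00141"], ["C00123", "C00233"], ["C00407", "C00233"],
        ["C00141", "C00233"]
      ]
    },
    {
      "id": "pw_gly_ser_thr",
      "name": "Glycine, serine and threonine metabolism",
      "nodes": ["C00037", "C00065", "C00188", "C00719", "C00213"],
      "edges": [
        ["C00719", "C00213"], ["C00213", "C00037"], ["C00065", "C00037"],
        ["C00188", "C00037"]
      ]
    },
    {
      "id": "pw_tca",
      "name": "Citrate cycle",
      "nodes": ["C00158", "C00026", "C00042", "C00122", "C00149", "C00036"],
      "edges": [
        ["C00158", "C00026"], ["C00026", "C00042"], ["C00042", "C00122"],
        ["C00122", "C00149"], ["C00149", "C00036"], ["C00036", "C00158"]
      ]
    },
    {
      "id": "pw_pyruvate",
      "name": "Pyruvate metabolism",
      "nodes": ["C00022", "C00186", "C00033", "C00024"],
      "edges": [
        ["C00022", "C00186"], ["C00022", "C00033"], ["C00022", "C00024"]
      ]
    },
    {
      "id": "pw_creatinine",
      "name": "Arginine and creatinine metabolism",
      "nodes": ["C00300", "C02305", "C00791", "C02565"],
      "edges": [
        ["C00300", "C02305"], ["C00300", "C00791"], ["C00791", "C02565"]
      ]
    },
    {
      "id": "pw_histidine",
      "name": "Histidine metabolism",
      "nodes": ["C00135", "C00386", "C01152", "C00785"],
      "edges": [
        ["C00135", "C00386"], ["C00135", "C00785"], ["C00386", "C01152"]
      ]
    },
    {
      "id": "pw_nicotinamide",
      "name": "Nicotinate and nicotinamide metabolism",
      "nodes": ["C00003", "C00153", "C02918"],
      "edges": [
        ["C00003", "C00153"], ["C00153", "C02918"]
      ]
    },
    {
      "id": "pw_taurine",
      "name": "Taurine and hypotaurine metabolism",
      "nodes": ["C00097", "C00519", "C00245"],
      "edges": [
        ["C00097", "C00519"], ["C00519", "C00245"]
      ]
    },
    {
      "id": "pw_butanoate",
      "name": "Butanoate metabolism",
      "nodes": ["C00246", "C00164", "C01089"],
      "edges": [
        ["C00246", "C00164"], ["C00164", "C01089"]
      ]
    }
  ]
}
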