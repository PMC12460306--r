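{
  "_comment": "Synthetic identity tables: locale-keyed name lists plus occupation and address components. All names and addresses are fabricated; locale weighting comes from the population configuration.",
  "locales": {
    "english": {
      "first_names": {
        "female": ["Emily", "Hannah", "Olivia", "Grace", "Chloe", "Sophie", "Megan", "Laura", "Rachel", "Claire"],
        "male": ["James", "Daniel", "Matthew", "Liam", "Owen", "Nathan", "Ethan", "Thomas", "Ryan", "Adam"]
      },
      "last_names": ["Miller", "Thompson", "Anderson", "Clarke", "Mitchell", "Bennett", "Harrison", "Fraser", "Watson", "Reid", "Campbell", "Stewart"]
    },
    "chinese": {
      "first_names": {
        "female": ["Mei", "Ling", "Xiu", "Yan", "Hua", "Jia", "Wen", "Li", "Fang", "Min"],
        "male": ["Wei", "Jun", "Hao", "Ming", "Lei", "Tao", "Feng", "Bo", "Kai", "Cheng"]
      },
      "last_names": ["Wang", "Li", "Zhang", "Chen", "Liu", "Yang", "Huang", "Wu", "Zhou", "Xu", "Lin", "Ho"]
    },
    "punjabi": {
      "first_names": {
        "female": ["Simran", "Harleen", "Jasleen", "Navdeep", "Gurpreet", "Kiran", "Manpreet", "Amrit", "Rajdeep", "Sukhman"],
        "male": ["Arjun", "Harpreet", "Gurdeep", "Jaspal", "Manjit", "Rajinder", "Sukhdev", "Baldev", "Kulwinder", "Amarjit"]
      },
      "last_names": ["Singh", "Kaur", "Gill", "Sandhu", "Dhillon", "Sidhu", "Grewal", "Brar", "Mann", "Bains", "Cheema", "Randhawa"]
    },
    "french": {
      "first_names": {
        "female": ["Camille", "Amelie", "Juliette", "Elodie", "Margaux", "Celine", "Noemie", "Sylvie", "Manon", "Adele"],
        "male": ["Luc", "Mathieu", "Olivier", "Etienne", "Julien", "Pascal", "Remy", "Thierry", "Laurent", "Marcel"]
      },
      "last_names": ["Tremblay", "Gagnon", "Roy", "Bouchard", "Gauthier", "Morin", "Lavoie", "Fortin", "Pelletier", "Bergeron", "Leclerc", "Girard"]
    }
  },
  "occupations": ["Software Developer", "Registered Nurse", "Retail Supervisor", "Elementary School Teacher", "Accountant", "Barista", "Construction Labourer", "Graphic Designer", "Warehouse Associate", "Administrative Assistant", "Chef", "Electrician", "Social Worker", "Delivery Driver", "Dental Hygienist", "Marketing Coordinator", "Landscaper", "Pharmacist", "Bus Operator", "Research Technician"],
  "streets": ["Oak Street", "Maple Avenue", "Hemlock Drive", "Cedar Lane", "Birchwood Crescent", "Granville Row", "Fraser Way", "Kingsway Court", "Cambie Place", "Arbutus Road", "Willow Terrace", "Dogwood Boulevard"],
  "cities": ["Vancouver, BC", "Burnaby, BC", "Surrey, BC", "Richmond, BC", "Coquitlam, BC", "North Vancouver, BC"]
}
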