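pattern,class
no ?data,no data
lights? at night|night ?time lights?|nightlights?|ntl|dmsp|viirs,built environment and urban/suburban proxies
building footprints?,built environment and urban/suburban proxies
built env|urban areas? ?\+ ?.*rural|urban and rural settlement,built environment and urban/suburban proxies
global human settlement|settlement layer|ghsl|schneider|modis urban|urban extents?|suburban extents?,urban/suburban extents
classified populated place|settlement hierarchy|hierarch|city|town|village,classified populated place
populated places?|gazetteer,populated place
roads?|railways?|railroads?|highways?|transport,transportation networks
elevation|slope|temperature|precipitation|climat|net primary|npp|topograph|dem\b,climatic/environmental
schools?|police|nutrition|health|hospital|clinic|facilit,facilities and services
pois?\b|places,places and POIs
water|rivers?|waterways?|waterbod|lakes?|streams?|coast,rivers/waterbodies/waterways
non ?residential|industr|farms?|commercial,non-residential land use
residential,residential land use
protected|wdpa,protected land use
land ?use|classified lu|\blu\b,general classified land use
cultivated|managed|cropland|agricult,cultivated/managed land cover
bare surface|bare soil|barren,natural bare surfaces land cover
urban|artificial surface|rural settlement,artificial surface land cover
vegetation|veg\b|forest|woody|shrub|herbaceous|grass|aquatic veg,natural/semi-natural vegetation land cover
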