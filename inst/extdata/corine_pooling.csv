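class_code,class_name,pooled_category
111,Continuous urban fabric,other_sea
112,Discontinuous urban fabric,other_sea
121,Industrial or commercial units,other_sea
122,Road and rail networks and associated land,other_sea
123,Port areas,other_sea
124,Airports,other_sea
131,Mineral extraction sites,other_sea
132,Dump sites,other_sea
133,Construction sites,other_sea
141,Green urban areas,other_sea
142,Sport and leisure facilities,other_sea
211,Non-irrigated arable land,agriculture
212,Permanently irrigated land,agriculture
213,Rice fields,agriculture
221,Vineyards,agriculture
222,Fruit trees and berry plantations,agriculture
223,Olive groves,agriculture
231,Pastures,agriculture
241,Annual crops associated with permanent crops,agriculture
242,Complex cultivation patterns,agriculture
243,Land principally occupied by agriculture with significant areas of natural vegetation,agriculture
244,Agro-forestry areas,agriculture
311,Broad-leaved forest,deciduous_forest
312,Coniferous forest,other_forest
313,Mixed forest,other_forest
321,Natural grasslands,mountain_vegetation
322,Moors and heathland,mountain_vegetation
323,Sclerophyllous vegetation,other_sea
324,Transitional woodland-shrub,other_forest
331,Beaches dunes sands,other_sea
332,Bare rocks,sparse_mountain
333,Sparsely vegetated areas,sparse_mountain
334,Burnt areas,other_sea
335,Glaciers and perpetual snow,other_sea
411,Inland marshes,wetlands
412,Peat bogs,wetlands
421,Salt marshes,other_sea
422,Salines,other_sea
423,Intertidal flats,other_sea
511,Water courses,inland_waters
512,Water bodies,inland_waters
521,Coastal lagoons,other_sea
522,Estuaries,other_sea
523,Sea and ocean,other_sea
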