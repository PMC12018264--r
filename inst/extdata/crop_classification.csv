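crop_id,crop_name,food_crop,group
whea,wheat,TRUE,cereals
rice,rice,TRUE,cereals
maiz,maize,TRUE,cereals
barl,barley,TRUE,cereals
pmil,pearl millet,TRUE,cereals
smil,small millet,TRUE,cereals
sorg,sorghum,TRUE,cereals
ocer,other cereals,TRUE,cereals
pota,potato,TRUE,starchy roots
swpo,sweet potato,TRUE,starchy roots
yams,yams,TRUE,starchy roots
cass,cassava,TRUE,starchy roots
orts,other roots,TRUE,starchy roots
bean,bean,TRUE,pulses
chic,chickpea,TRUE,pulses
cowp,cowpea,TRUE,pulses
pige,pigeon pea,TRUE,pulses
lent,lentil,TRUE,pulses
opul,other pulses,TRUE,pulses
soyb,soybean,TRUE,oil crops
grou,groundnut,TRUE,oil crops
cnut,coconut,TRUE,oil crops
bana,banana,TRUE,fruits and vegetables
plnt,plantain,TRUE,fruits and vegetables
trof,tropical fruit,TRUE,fruits and vegetables
temf,temperate fruit,TRUE,fruits and vegetables
vege,vegetables,TRUE,fruits and vegetables
toma,tomato,TRUE,fruits and vegetables
onio,onion,TRUE,fruits and vegetables
citr,citrus,TRUE,fruits and vegetables
oilp,oil palm,FALSE,
sunf,sunflower,FALSE,
rape,rapeseed,FALSE,
sesa,sesame seed,FALSE,
ooil,other oil crops,FALSE,
oliv,olive,FALSE,
sugc,sugarcane,FALSE,
sugb,sugar beet,FALSE,
cott,cotton,FALSE,
ofib,other fibre crops,FALSE,
acof,arabica coffee,FALSE,
rcof,robusta coffee,FALSE,
coco,cocoa,FALSE,
teas,tea,FALSE,
toba,tobacco,FALSE,
rest,rest of crops,FALSE,
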