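item_id,nova_group,nova_subgroup,note
fruit_fresh,1,fruits,whole fruit; minimal processing
veg_raw,1,vegetables,raw or home-cooked vegetables
rice_cooked,1,grains,plain cooked grains
oatmeal,1,grains,plain rolled oats cooked with water or milk
beans,1,legumes,dried or home-cooked legumes
nuts,1,nuts_and_seeds,plain nuts and seeds
chicken,1,meat_and_poultry,fresh poultry
fish,1,fish_and_seafood,fresh fish
eggs,1,eggs,shell eggs
salad,1,vegetables,leafy salad without dressing
milk,1,milk_and_plain_yogurt,plain fluid milk
coffee,1,coffee_and_tea,brewed coffee or tea
juice100,1,fruits,juice pressed from fruit with nothing added
sugar_added,2,table_sugar_and_honey,culinary sweetener added at table
butter,2,butter_and_lard,culinary fat
cheese,3,cheese,processed by salting and fermentation
canned_veg,3,canned_vegetables_and_legumes,preserved in brine
canned_fruit,3,canned_fruit,preserved in syrup
ham,3,cured_meats,salted and cured whole cuts
soda,4,soft_drinks,industrial formulation with added sugars and additives
fruit_drink,4,fruit_drinks,reconstituted flavored drink
bread,4,breads,US market bread; industrially made with additives
cereal,4,breakfast_cereals,extruded and sweetened
cake,4,cakes_cookies_and_pies,industrial baked goods
chips,4,salty_snacks,fried snack with flavorings
candy,4,candy_and_chocolate,confectionery
icecream,4,ice_cream_and_desserts,industrial frozen dessert
pizza,4,instant_and_ready_dishes,ready-to-heat dish
hotdog,4,reconstituted_meats,meat product from remnants and additives
yogurt_sweet,4,sweetened_dairy,dairy with added sugar and flavoring
margarine,4,margarine_and_spreads,hydrogenated fat spread
dressing,4,sauces_and_dressings,emulsified dressing with additives
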